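# standardization schemes and the two-head fusion MLP

test_that("standardization uses population moments and round-trips", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f"))
  st <- fit_standardizer(x, "across_rounds")
  z <- apply_standardizer(st, x)
  expect_equal(as.numeric(z), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(invert_standardizer(st, z), x, tolerance = 1e-12)
  # already standardized data maps to itself
  st2 <- fit_standardizer(z, "across_rounds")
  expect_equal(apply_standardizer(st2, z), z, tolerance = 1e-12)
  expect_error(fit_standardizer(matrix(1, 5, 1, dimnames = list(NULL, "c")),
                                "across_rounds"), "zero variance.*c")
})

test_that("per-round standardization normalizes each round separately", {
  x <- matrix(c(rnorm(50, 5, 2), rnorm(50, -3, 0.5)), 100, 1,
              dimnames = list(NULL, "phi"))
  rounds <- rep(c("a", "b"), each = 50)
  st <- fit_standardizer(x, "per_round", rounds)
  z <- apply_standardizer(st, x, rounds)
  for (r in c("a", "b")) {
    expect_equal(mean(z[rounds == r, 1]), 0, tolerance = 1e-12)
    expect_equal(mean(z[rounds == r, 1]^2), 1, tolerance = 1e-12)
  }
  expect_error(apply_standardizer(st, x[1:2, , drop = FALSE], c("a", "zz")),
               "zz")
})

test_that("the network has the published shapes and a seeded build is reproducible", {
  m <- build_network(network_spec(), seed = 7)
  shapes <- lapply(m$W, dim)
  expect_equal(shapes, list(c(10L, 16L), c(21L, 128L), c(128L, 64L),
                            c(64L, 32L), c(32L, 16L), c(16L, 1L)))
  expect_true(all(vapply(m$b, function(b) all(b == 0), logical(1))))
  m2 <- build_network(network_spec(), seed = 7)
  expect_identical(m, m2)
  expect_false(identical(m, build_network(network_spec(), seed = 8)))
  # zero-weight network outputs exactly 1/2 everywhere
  m0 <- m
  m0$W <- lapply(m0$W, function(w) w * 0)
  p <- predict_network(m0, matrix(0, 4, 10), matrix(0, 4, 5))
  expect_equal(p$prob, rep(0.5, 4))
  expect_error(network_spec(class_widths = c(128, 64, 32)), "16")
  expect_error(network_spec(class_widths = c(128, 96, 16)), "halve")
})

make_separable <- function(n, seed) {
  set.seed(seed)
  pr <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("p", 1:10)))
  mod <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- as.numeric(mod[, 1] + 0.5 * mod[, 2] - 0.3 * mod[, 3] > 0)
  list(pr = pr, mod = mod, y = y)
}

test_that("training separates separable data and honors the early-stop contract", {
  d <- make_separable(1200, 1)
  tr <- 1:900; va <- 901:1200
  cfg <- train_config(seed = 2)
  fit <- train_network(build_network(seed = 1), d$pr[tr, ], d$mod[tr, ], d$y[tr],
                       d$pr[va, ], d$mod[va, ], d$y[va], cfg)
  p_tr <- predict_network(fit$model, d$pr[tr, ], d$mod[tr, ])
  expect_gt(mean((p_tr$prob >= 0.5) == d$y[tr]), 0.97)
  p_va <- predict_network(fit$model, d$pr[va, ], d$mod[va, ])
  expect_gt(mean((p_va$prob >= 0.5) == d$y[va]), 0.95)
  h <- fit$history
  expect_lte(nrow(h), cfg$max_epochs)
  if (nrow(h) < cfg$max_epochs)
    expect_equal(nrow(h), fit$best_epoch + cfg$patience)
  expect_true(all(p_va$prob > 0 & p_va$prob < 1))
})

test_that("class weights follow inverse frequency and training is deterministic", {
  d <- make_separable(400, 3)
  half <- d$y == 1
  # force exact balance by trimming
  keep <- c(which(half)[1:100], which(!half)[1:100])
  fit <- train_network(build_network(seed = 1),
                       d$pr[keep, ], d$mod[keep, ], d$y[keep],
                       d$pr[keep, ], d$mod[keep, ], d$y[keep],
                       train_config(max_epochs = 3, patience = 2, seed = 5))
  expect_equal(unname(fit$class_weights), c(1, 1))
  # 3:1 imbalance: weights N/(2*Nc)
  keep2 <- c(which(half)[1:150], which(!half)[1:50])
  fit2 <- train_network(build_network(seed = 1),
                        d$pr[keep2, ], d$mod[keep2, ], d$y[keep2],
                        d$pr[keep2, ], d$mod[keep2, ], d$y[keep2],
                        train_config(max_epochs = 3, patience = 2, seed = 5))
  expect_equal(unname(fit2$class_weights), c(200 / 100, 200 / 300))
  expect_error(train_network(build_network(seed = 1),
                             d$pr[half, ], d$mod[half, ], d$y[half],
                             d$pr, d$mod, d$y, train_config()),
               "both classes")
  # identical seeds give identical histories
  args <- list(d$pr[keep2, ], d$mod[keep2, ], d$y[keep2],
               d$pr[keep, ], d$mod[keep, ], d$y[keep],
               train_config(max_epochs = 10, patience = 5, seed = 9))
  f1 <- do.call(train_network, c(list(build_network(seed = 4)), args))
  f2 <- do.call(train_network, c(list(build_network(seed = 4)), args))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model, f2$model)
})

test_that("prediction thresholds behave and unstandardized input warns", {
  d <- make_separable(50, 6)
  m <- build_network(seed = 2)
  p <- predict_network(m, d$pr, d$mod, threshold = 0)
  expect_true(all(p$label))
  expect_warning(predict_network(m, d$pr + 50, d$mod), "standardized")
})

test_that("models and standardizers round-trip through JSON", {
  m <- build_network(seed = 3)
  x <- matrix(rnorm(40), 4, 10, dimnames = list(NULL, paste0("p", 1:10)))
  st <- fit_standardizer(x, "across_rounds")
  path <- withr::local_tempfile(fileext = ".json")
  save_model_json(m, path, standardizers = list(pulsation = st))
  back <- load_model_json(path)
  expect_equal(back$model$W, m$W, tolerance = 1e-12)
  d <- make_separable(20, 7)
  expect_equal(predict_network(back$model, d$pr, d$mod)$prob,
               predict_network(m, d$pr, d$mod)$prob, tolerance = 1e-10)
  expect_equal(unname(back$standardizers$pulsation$means), unname(st$means),
               tolerance = 1e-12)
})
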