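# Small dimensions keep these end-to-end tests fast; the architecture and
# code paths are identical at production sizes.
small_cfg <- function(seed = 2, ...)
  coformer_config(d_latent = 8, d_c = 4, d_combined = 8, d_h = 4,
                  epochs = 60, seed = seed, ...)

test_that("variant wiring: parameter census and input sensitivity", {
  cfg <- small_cfg()
  m_full <- build_model("coformersurv", c(6, 5), cfg)
  expect_true(all(c("head1.Wq", "head2.Wq", "W1c", "smp.Wq", "W1", "beta")
                  %in% names(m_full$params)))
  # crosst drops the inter-sample attention weights
  m_ct <- build_model("crosst", c(6, 5), cfg)
  expect_false(any(c("smp.Wq", "smp.Wv") %in% names(m_ct$params)))
  expect_equal(length(m_ct$params$beta), cfg$d_combined)
  # mgt drops the inter-omics block
  m_mgt <- build_model("mgt", c(6, 5), cfg)
  expect_false(any(grepl("^head", names(m_mgt$params))))
  expect_error(build_model("nope", c(6, 5), cfg))

  # sgt ignores the second omics entirely
  omics <- make_toy_omics(n = 14, p = c(6, 5), seed = 9)
  X <- lapply(omics, function(m) m$values)
  g1 <- build_fused_graph(X[1], K = 3)
  m_sgt <- build_model("sgt", c(6, 5), small_cfg())
  s1 <- predict_risk(m_sgt, X, g1)
  X2 <- X; X2[[2]] <- X2[[2]] + matrix(rnorm(70, sd = 5), 14, 5)
  expect_identical(predict_risk(m_sgt, X2, g1), s1)

  # full model smoke: finite scores end-to-end on a 10-sample toy
  omics10 <- make_toy_omics(n = 10, p = c(6, 5), seed = 10)
  X10 <- lapply(omics10, function(m) m$values)
  g10 <- build_fused_graph(X10, K = 3)
  s10 <- predict_risk(build_model("coformersurv", c(6, 5), small_cfg()),
                      X10, g10)
  expect_length(s10, 10)
  expect_true(all(is.finite(s10)))

  # generalizes beyond two omics: three layers end-to-end
  omics3 <- make_toy_omics(n = 12, p = c(6, 5, 4), seed = 12)
  X3 <- lapply(omics3, function(m) m$values)
  g3 <- build_fused_graph(X3, K = 3)
  m3 <- build_model("coformersurv", c(6, 5, 4), small_cfg())
  s3 <- predict_risk(m3, X3, g3)
  expect_length(s3, 12)
  expect_true(all(is.finite(s3)))
})

test_that("training descends the partial likelihood and is reproducible; lr 0 freezes parameters", {
  omics <- make_toy_omics(n = 30, p = c(8, 6), seed = 21)
  X <- lapply(omics, function(m) scale(m$values))
  surv <- make_toy_surv(30, seed = 21)
  g <- build_fused_graph(X, K = 5)
  cfg <- small_cfg(seed = 4)
  m <- build_model("coformersurv", c(8, 6), cfg)
  fit <- fit_model(m, X, surv, g)
  expect_true(all(is.finite(fit$trace)))
  expect_lt(fit$trace[length(fit$trace)], fit$trace[1])

  fit2 <- fit_model(build_model("coformersurv", c(8, 6), cfg), X, surv, g)
  expect_identical(fit$params, fit2$params)

  m0 <- build_model("coformersurv", c(8, 6), cfg)
  fit0 <- fit_model(m0, X, surv, g, lr = 0)
  expect_identical(fit0$params, m0$params)

  expect_error(fit_model(m, X, survival_table(surv$sample_id, surv$time,
                                              rep(0, 30)), g),
               "at least one event")
})

test_that("model gradients match finite differences for every variant", {
  set.seed(42)
  n <- 12
  X <- list(matrix(rnorm(n * 5), n, 5), matrix(rnorm(n * 4), n, 4))
  surv <- make_toy_surv(n, seed = 42)
  cfg <- coformer_config(n_heads = 2, d_latent = 4, d_c = 3,
                         d_combined = 6, d_h = 3, activation = "tanh",
                         seed = 7)
  graph <- build_fused_graph(X, K = 3)
  loss_at <- function(model, P) {
    model$params <- P
    fw <- coformersurv:::.forward(model, X, graph)
    coformersurv:::.cox_loss_grad(fw$scores, surv$time, surv$event,
                                  "inclusive", want_grad = FALSE)$loss
  }
  for (v in c("coformersurv", "sgt", "mgt", "crosst", "crosst_segcn",
              "crosst_sa")) {
    m <- build_model(v, c(5, 4), cfg)
    m$params$beta <- rnorm(length(m$params$beta), sd = 0.5)
    fw <- coformersurv:::.forward(m, X, graph, want_cache = TRUE)
    lg <- coformersurv:::.cox_loss_grad(fw$scores, surv$time, surv$event,
                                        "inclusive")
    G <- coformersurv:::.backward(m, fw$cache, lg$grad)
    for (k in names(m$params)) {
      w <- m$params[[k]]
      idx <- seq_along(w)
      if (length(idx) > 6) idx <- sample(idx, 6)
      for (i in idx) {
        h <- 1e-5
        Pp <- m$params; Pp[[k]][i] <- Pp[[k]][i] + h
        Pm <- m$params; Pm[[k]][i] <- Pm[[k]][i] - h
        fd <- (loss_at(m, Pp) - loss_at(m, Pm)) / (2 * h)
        expect_lt(abs(fd - G[[k]][i]), 1e-6)
      }
    }
  }
})

test_that("repeated holdout returns per-repeat metrics and is seed-reproducible", {
  co <- simulate_cohort(sim_config(n = 60, p = c(10, 8), seed = 31))
  r1 <- suppressWarnings(repeated_holdout(co$omics, co$survival,
                                          variant = "crosst",
                                          cfg = small_cfg(), n_repeats = 3,
                                          seed = 9))
  expect_equal(nrow(r1$repeats), 3)
  expect_equal(unique(r1$repeats$n_test), 12)     # 20% of 60
  expect_true(all(r1$repeats$c_index >= 0 & r1$repeats$c_index <= 1))
  r2 <- suppressWarnings(repeated_holdout(co$omics, co$survival,
                                          variant = "crosst",
                                          cfg = small_cfg(), n_repeats = 3,
                                          seed = 9))
  expect_identical(r1$repeats, r2$repeats)
})

test_that("select_K returns the grid argmax with ties to the smaller K", {
  co <- simulate_cohort(sim_config(n = 50, p = c(8, 6), seed = 41))
  one <- suppressWarnings(select_K(co$omics, co$survival, grid = 5,
                                   variant = "crosst_segcn",
                                   cfg = small_cfg(), folds = 2))
  expect_equal(one$best_K, 5)
  sk <- suppressWarnings(select_K(co$omics, co$survival, grid = c(4, 8),
                                  variant = "crosst_segcn",
                                  cfg = small_cfg(), folds = 2))
  expect_true(sk$best_K %in% c(4, 8))
  # the tie rule itself
  cv <- data.frame(K = c(10, 15), c_index = c(0.7, 0.7))
  ord <- order(-cv$c_index, cv$K)
  expect_equal(cv$K[ord[1]], 10)
})

test_that("hidden-node correlation analysis recovers planted features", {
  set.seed(51)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  Zh <- cbind(X[, 3], rnorm(n))         # node 1 is exactly feature g3
  tab <- feature_correlation_analysis(X, Zh, top_m = 2)
  expect_equal(tab$feature[tab$node == 1][1], "g3")
  expect_equal(tab$r[tab$node == 1][1], 1, tolerance = 1e-12)

  # hand-computed Pearson on a 5-sample toy
  x <- c(1, 2, 4, 7, 11); z <- c(2, 1, 5, 4, 8)
  r_hand <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  tab2 <- feature_correlation_analysis(matrix(x, 5, 1,
                                              dimnames = list(NULL, "f")),
                                       matrix(z, 5, 1), top_m = 1)
  expect_equal(tab2$r[1], r_hand, tolerance = 1e-12)

  # zero-variance hidden node is skipped with a warning
  expect_warning(t3 <- feature_correlation_analysis(X, cbind(X[, 1], 0),
                                                    top_m = 1),
                 "zero variance")
  expect_equal(unique(t3$node), 1)
})

test_that("serialization round-trip reproduces identical predictions", {
  omics <- make_toy_omics(n = 20, p = c(6, 5), seed = 61)
  X <- lapply(omics, function(m) scale(m$values))
  surv <- make_toy_surv(20, seed = 61)
  g <- build_fused_graph(X, K = 4)
  fit <- fit_model(build_model("coformersurv", c(6, 5), small_cfg(seed = 3)),
                   X, surv, g, epochs = 30)
  path <- tempfile(fileext = ".rds")
  write_model(fit, path)
  re <- read_model(path)
  expect_identical(predict_risk(re, X, g), predict_risk(fit, X, g))
  unlink(path)
})

test_that("held-out outcomes never influence training (taint check)", {
  co <- simulate_cohort(sim_config(n = 50, p = c(8, 6), seed = 71))
  tr <- 1:40; te <- 41:50
  fit1 <- suppressWarnings(coformersurv:::.fit_split(
    co$omics, co$survival, tr, te, "coformersurv", small_cfg(), K = 5))
  # permute the held-out outcomes: trained parameters must be unchanged
  surv_perm <- co$survival
  set.seed(1)
  perm <- sample(te)
  surv_perm$time[te] <- co$survival$time[perm]
  surv_perm$event[te] <- co$survival$event[perm]
  fit2 <- suppressWarnings(coformersurv:::.fit_split(
    co$omics, co$survival, tr, te, "coformersurv", small_cfg(), K = 5))
  fit3 <- suppressWarnings(coformersurv:::.fit_split(
    co$omics, surv_perm, tr, te, "coformersurv", small_cfg(), K = 5))
  expect_identical(fit2$model$params, fit1$model$params)
  expect_identical(fit3$model$params, fit1$model$params)
  expect_identical(fit3$test_scores, fit1$test_scores)
})
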