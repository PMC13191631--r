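test_that("Benjamini-Hochberg matches step-up enumeration", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06)
  out <- bh_fdr(p, alpha = 0.05)
  expect_equal(sum(out$reject), 2)
  expect_equal(out$reject, bh_stepup(p, 0.05))
  expect_true(all(out$adjusted >= p))

  set.seed(40)
  for (i in 1:20) {
    pv <- runif(sample(3:30, 1))^sample(1:3, 1)
    a <- runif(1, 0.01, 0.2)
    expect_equal(bh_fdr(pv, a)$reject, bh_stepup(pv, a))
  }

  allone <- bh_fdr(rep(1, 5), 0.05)
  expect_equal(sum(allone$reject), 0)
  expect_true(all(allone$adjusted == 1))
  expect_true(bh_fdr(0.025, 0.05)$reject)   # m = 1 reduces to raw threshold
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("noiseless regression recovers the planted map exactly", {
  set.seed(41)
  x <- rnorm(100)
  # lm warns about the essentially perfect fit; that is the point here
  rep1 <- suppressWarnings(fit_symptom_glm(data.frame(x = x), 2 * x))
  expect_equal(rep1$r_squared, 1)
  # predictors are z-scored: coefficient is 2 * sd(x)
  expect_equal(rep1$table$beta, 2 * sd(x), tolerance = 1e-10)
  expect_true(rep1$table$sig)
})

test_that("planted effects among 15 features are detected with correct sign", {
  set.seed(42)
  n <- 2000
  feats <- as.data.frame(matrix(rnorm(n * 15), n))
  names(feats) <- sprintf("f%02d", 1:15)
  y <- 3 * feats$f03 - 3 * feats$f11 + rnorm(n, sd = 1)
  cov <- data.frame(participant = rep(c("P01", "P02"), n / 2),
                    hemisphere = rep(c("L", "L", "R", "R"), n / 4))
  rep1 <- fit_symptom_glm(feats, y, cov)
  tab <- rep1$table
  expect_true(tab$sig[tab$predictor == "f03"])
  expect_true(tab$sig[tab$predictor == "f11"])
  expect_gt(tab$t[tab$predictor == "f03"], 0)
  expect_lt(tab$t[tab$predictor == "f11"], 0)
  expect_false(any(tab$sig[!tab$predictor %in% c("f03", "f11")]))
  # null features' raw p-values look uniform
  ks <- ks.test(tab$p_raw[!tab$predictor %in% c("f03", "f11")], "punif")
  expect_gt(ks$p.value, 0.01)
  # t statistics are invariant to affine rescaling of one predictor
  feats2 <- feats; feats2$f03 <- 10 * feats2$f03 + 5
  rep2 <- fit_symptom_glm(feats2, y, cov)
  expect_equal(rep2$table$t, rep1$table$t, tolerance = 1e-10)
  expect_equal(rep2$r_squared, rep1$r_squared, tolerance = 1e-12)
})

test_that("permuted responses yield no significant predictors", {
  set.seed(43)
  n <- 300
  feats <- as.data.frame(matrix(rnorm(n * 15), n))
  y <- 3 * feats$V1 + rnorm(n)
  hits <- vapply(1:100, function(i) {
    any(fit_symptom_glm(feats, sample(y))$table$sig)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("rank deficiency and constant columns are reported by name", {
  set.seed(44)
  f <- data.frame(a = rnorm(50), b = rnorm(50))
  f$c <- f$a + f$b
  expect_error(fit_symptom_glm(f, rnorm(50)), "collinear.*c")
  expect_error(fit_symptom_glm(data.frame(a = rnorm(50), k = 1), rnorm(50)),
               "constant.*k")
})

test_that("state-resolved model handles missing windows and relabelling", {
  set.seed(45)
  n <- 400; K <- 4
  feats <- as.data.frame(matrix(rnorm(n * 15 * K), n))
  names(feats) <- unlist(lapply(1:K, function(k)
    paste0(sprintf("state%d_", k),
           c(outer(names(band_scheme()), c("stn", "ctx", "coh"),
                   function(b, r) paste0(r, "_", b))))))
  y <- 2.5 * feats$state2_coh_high_beta + rnorm(n)
  # the 60-column table is exactly what run_state_model assembles
  rep1 <- fit_symptom_glm(feats, y)
  tab <- rep1$table
  expect_equal(nrow(tab), 60)
  expect_true(tab$sig[tab$predictor == "state2_coh_high_beta"])
  twins <- sprintf("state%d_coh_high_beta", c(1, 3, 4))
  expect_false(any(tab$sig[tab$predictor %in% twins]))

  # permuting the state blocks permutes the report rows with it
  perm_names <- sub("^state2", "stateX", names(feats))
  perm_names <- sub("^state4", "state2", perm_names)
  perm_names <- sub("^stateX", "state4", perm_names)
  feats_p <- feats; names(feats_p) <- perm_names
  rep2 <- fit_symptom_glm(feats_p[names(feats)], y)
  expect_equal(rep2$table$t[rep2$table$predictor == "state4_coh_high_beta"],
               rep1$table$t[rep1$table$predictor == "state2_coh_high_beta"],
               tolerance = 1e-12)
})

test_that("temporal models are fit separately per state and metric", {
  set.seed(46)
  K <- 4; n_win <- 300
  tabs <- lapply(1:K, function(k) {
    fo <- runif(n_win, 0.1, 0.4)
    data.frame(session = "P01_L", window = seq_len(n_win),
               participant = rep(c("P01", "P02"), each = n_win / 2),
               hemisphere = "L",
               bradykinesia = NA, dyskinesia = 0, tremor = 0,
               state = k, fo = fo,
               mean_lifetime_s = runif(n_win, 0.5, 2),
               mean_interval_s = runif(n_win, 1, 5),
               switching_rate_hz = NA, n_visits = 5L)
  })
  mt <- do.call(rbind, tabs)
  # plant: bradykinesia decreases with state-1 FO only
  mt$bradykinesia <- 50 - 40 * ifelse(mt$state == 1, mt$fo, 0) +
    rnorm(nrow(mt), sd = 1) + 40 * 0.25
  rep1 <- run_temporal_models(mt, "bradykinesia")
  expect_equal(nrow(rep1$table), 12)   # 4 states x 3 metrics
  s1 <- rep1$table[rep1$table$predictor == "state1_fo", ]
  expect_true(s1$sig)
  expect_lt(s1$t, 0)
  others <- rep1$table[rep1$table$predictor != "state1_fo", ]
  expect_false(any(others$sig))

  # correlated metrics of one state do not break anything: separate fits
  mt2 <- mt
  mt2$mean_lifetime_s <- mt2$fo * 4          # perfectly collinear pair
  mt2$bradykinesia <- 50 - 40 * ifelse(mt2$state == 1, mt2$fo, 0) +
    rnorm(nrow(mt2), sd = 0.5)
  rep2 <- run_temporal_models(mt2, "bradykinesia")
  t2 <- rep2$table
  expect_true(t2$sig[t2$predictor == "state1_fo"])
  expect_true(t2$sig[t2$predictor == "state1_mean_lifetime_s"])
})
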