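# Reduced problem sizes keep these runs to seconds; the full-scale search
# is exercised by the acceptance suite.

test_that("step 1 pools a deep intermediate and reports restart stubs", {
  cx <- make_toy_complex()
  starts <- replicate(3, cx$coords, simplify = FALSE)
  pool <- step1_unbind(cx, starts, alpha1 = 100, time_limit = 2500,
                       params = langevin_params(seed = 41))
  expect_s3_class(pool, "candidate_pool")
  expect_gt(length(pool$segments) + length(pool$restarts), 0)
  for (s in pool$segments) {
    expect_gt(s$lifetime, 150)
    # pooled states sit away from the bound well
    expect_gt(abs(s$mean_rho - cx$bound_rho), 1)
  }
})

test_that("step 1 with zero bias leaves a high-barrier system bound", {
  cx <- make_toy_complex()
  starts <- list(cx$coords, cx$coords)
  pool <- step1_unbind(cx, starts, alpha1 = 0, time_limit = 300,
                       params = langevin_params(seed = 43))
  expect_length(pool$segments, 0)
  for (l in pool$log) expect_equal(l$status, "time_limit")
})

test_that("a landscape without an intermediate yields an empty pool", {
  cx <- make_toy_complex(inter_depth = 0)
  starts <- replicate(3, cx$coords, simplify = FALSE)
  pool <- step1_unbind(cx, starts, alpha1 = 300, time_limit = 5000,
                       params = langevin_params(seed = 47))
  expect_length(pool$segments, 0)
  for (l in pool$log) expect_equal(l$status, "unbound")
})

test_that("step 2 pools the intermediate at a low force constant", {
  cx <- make_toy_complex()
  x0 <- cx$coords
  x0[6:9, 1] <- x0[6:9, 1] + (cx$inter_rho - cx$bound_rho)
  ext <- step2_extend(cx, x0, alpha_start = 50,
                      params = langevin_params(seed = 53),
                      time_limit = 3000)
  expect_equal(ext$outcome, "pooled")
  expect_gt(length(ext$segments), 0)
  expect_lt(abs(ext$segments[[1]]$mean_rho - cx$inter_rho), 1)
})

test_that("step 2 discards a rebound to the bound state", {
  cx <- make_toy_complex()
  # restart just outside the bound well with the watermark reset there:
  # a weak ratchet cannot hold the ligand out
  x0 <- cx$coords
  x0[6:9, 1] <- x0[6:9, 1] + 0.8
  ext <- step2_extend(cx, x0, alpha_start = 50,
                      params = langevin_params(seed = 59),
                      time_limit = 600)
  expect_equal(ext$outcome, "rebound")
  expect_length(ext$segments, 0)
})

test_that("step 2 walks the schedule to exhaustion on a barrierless path", {
  cx <- make_toy_complex(inter_depth = 0)
  x0 <- cx$coords
  x0[6:9, 1] <- x0[6:9, 1] + 4
  ext <- step2_extend(cx, x0, alpha_start = 250,
                      params = langevin_params(seed = 61),
                      time_limit = 2000)
  expect_equal(ext$outcome, "exhausted")
  alphas <- vapply(ext$attempts, function(a) a$alpha, numeric(1))
  expect_equal(alphas, seq(250, 50, by = -25))
})

fake_segment <- function(rho, means, run = 1, sds = 0.2) {
  structure(list(mean_rho = rho, run = run, alpha = 100,
                 means = means,
                 sds = setNames(rep(sds, length(means)), names(means)),
                 lifetime = 200),
            class = "metastable_segment")
}

fake_pool <- function(rhos, centers, jitter = 0.05, sds = 0.2) {
  chan <- c("dCM_core", "dCM_iBu", "dCM_Tol", "dCM_Ethe",
            "RMSD_core", "RMSD_iBu", "RMSD_Tol", "RMSD_Ethe",
            "RMSD_protein")
  segs <- lapply(seq_along(rhos), function(i) {
    m <- setNames(c(rep(centers[i], 4), rep(centers[i] - 4, 4), 0.3),
                  chan)
    m <- m + c(stats::rnorm(8, 0, jitter), 0)
    fake_segment(rhos[i], m, run = i, sds = sds)
  })
  structure(list(segments = segs, restarts = list(), log = list()),
            class = "candidate_pool")
}

test_that("step 3 accepts one tight cluster and reports its statistics", {
  set.seed(71)
  pool <- fake_pool(rhos = rep(9, 5), centers = rep(8.6, 5))
  rep3 <- step3_cluster(pool, bound_dcm_core = 4.6)
  expect_length(rep3$clusters, 1)
  expect_equal(rep3$accepted_id, 1L)
  cl <- rep3$clusters[["1"]]
  expect_true(all(cl$criteria))
  expect_lt(max(cl$ensemble_sd), 0.2) # sampling noise only
})

test_that("step 3 separates two wells and rejects a forced merger", {
  set.seed(73)
  pool <- fake_pool(rhos = c(rep(9, 3), rep(13, 3)),
                    centers = c(rep(8.6, 3), rep(12.6, 3)))
  rep3 <- step3_cluster(pool, bound_dcm_core = 4.6)
  expect_length(rep3$clusters, 2)
  # a forced single cluster shows ensemble SDs above 2 A and fails
  forced <- step3_cluster(pool, bound_dcm_core = 4.6, cutoff = 100)
  expect_length(forced$clusters, 1)
  expect_gt(max(forced$clusters[["1"]]$ensemble_sd), 2)
  expect_false(forced$clusters[["1"]]$accepted)
})

test_that("step 3 criteria decide a single-segment pool", {
  pool1 <- fake_pool(rhos = 9, centers = 8.6, jitter = 0)
  rep1 <- step3_cluster(pool1, bound_dcm_core = 4.6)
  expect_equal(rep1$accepted_id, 1L)
  # proximity criterion: a segment far outside the pocket is rejected
  poolfar <- fake_pool(rhos = 16, centers = 15.6, jitter = 0)
  repf <- step3_cluster(poolfar, bound_dcm_core = 4.6)
  expect_true(is.na(repf$accepted_id))
  expect_false(repf$clusters[["1"]]$criteria[["proximity"]])
  # unstable members fail criterion (i)
  poolus <- fake_pool(rhos = 9, centers = 8.6, jitter = 0, sds = 1.8)
  repu <- step3_cluster(poolus, bound_dcm_core = 4.6)
  expect_false(repu$clusters[["1"]]$criteria[["stable"]])
  expect_error(step3_cluster(structure(list(segments = list()),
                                       class = "candidate_pool"), 4.6),
               "empty")
})

test_that("the full search is deterministic for a fixed master seed", {
  cx <- make_toy_complex()
  r1 <- run_protocol(cx, n_starts = 2, seed = 5, time_limit = 1500,
                     max_restarts = 2L)
  r2 <- run_protocol(cx, n_starts = 2, seed = 5, time_limit = 1500,
                     max_restarts = 2L)
  expect_identical(r1$found, r2$found)
  expect_identical(length(r1$pool$segments), length(r2$pool$segments))
  if (!is.null(r1$report))
    expect_identical(r1$report$features, r2$report$features)
  # pooled lifetimes always exceed the 150 ps rule
  for (s in r1$pool$segments) expect_gt(s$lifetime, 150)
})
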