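# Shared toy system: 1 Mb circular genome, one occupied attB, markers placed
# one per headful window.
sim_system <- function(n_max = 7, H = 45000, direction = 1, seed = 101) {
  model <- prophage_model("simphage", H, n_max)
  spec <- genome_spec(
    length = 1e6, n_orfs = 0,
    attb_layout = data.frame(site_id = "att1", frac = 0.25,
                             direction = direction),
    markers = data.frame(marker_id = paste0("mk", seq_len(n_max)),
                         site_id = "att1", hf = seq_len(n_max),
                         offset = round(H / 2)),
    seed = seed)
  g <- generate_toy_genome(spec, model)
  list(genome = g, site = g$attb_sites$att1, model = model)
}

test_that("limiting cases behave deterministically", {
  sys <- sim_system()
  # no in-situ packaging, no ppac: the lysate is pure phage
  p0 <- simulation_params(n_donors = 200, p_in_situ = 0, seed = 1)
  lys0 <- simulate_lysate(sys$genome, sys$site, sys$model, p0)
  expect_true(all(lys0$particles$mode == "phage"))
  # q = 1: every LT series runs to n_max, covering windows 1..n_max
  p1 <- simulation_params(n_donors = 100, p_in_situ = 1,
                          series_continuation = 1, particles_per_donor = 10,
                          seed = 2)
  lys1 <- simulate_lysate(sys$genome, sys$site, sys$model, p1)
  expect_equal(nrow(lys1$particles), 100 * 10 * 7)
  expect_equal(as.integer(table(lys1$particles$series_index)), rep(1000L, 7))
  # r = 0: nothing recombines
  pr0 <- simulation_params(n_donors = 100, p_in_situ = 1,
                           recombination_prob = 0, seed = 3)
  out0 <- simulate_transduction(
    simulate_lysate(sys$genome, sys$site, sys$model, pr0),
    sys$genome$loci, pr0)
  expect_true(all(out0$per_marker$frequency == 0))
})

test_that("an identical seed reproduces the lysate and outcome exactly", {
  sys <- sim_system()
  params <- simulation_params(n_donors = 300, seed = 77,
                              ppac_sites = data.frame(
                                position = 9e5, direction = 1,
                                relative_efficiency = 1e-3))
  run <- function() {
    lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
    list(lys = lys$particles,
         out = simulate_transduction(lys, sys$genome$loci, params))
  }
  a <- run(); b <- run()
  expect_identical(a$lys, b$lys)
  expect_identical(a$out$per_marker, b$out$per_marker)
  expect_identical(a$out$lysogens_per_donor, b$out$lysogens_per_donor)
})

test_that("particle counts are conserved and transfers bounded by containment", {
  sys <- sim_system()
  params <- simulation_params(n_donors = 500, p_in_situ = 0.5,
                              recombination_prob = 0.5, seed = 5)
  lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
  # total particles = sum of series lengths; series = particles with index 1
  expect_equal(nrow(lys$particles), sum(lys$particles$series_index >= 1))
  n_series_drawn <- sum(lys$particles$series_index == 1)
  expect_equal(n_series_drawn, lys$n_series)
  out <- simulate_transduction(lys, sys$genome$loci, params)
  expect_true(all(out$per_marker$events_lt <= out$per_marker$contained_lt))
  expect_true(all(out$per_marker$events_gt <= out$per_marker$contained_gt))
})

test_that("series lengths follow the truncated geometric law", {
  sys <- sim_system()
  q <- 0.5
  params <- simulation_params(n_donors = 2000, particles_per_donor = 10,
                              p_in_situ = 1, series_continuation = q,
                              seed = 19)
  lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
  idx <- lys$particles$series_index
  n_series <- sum(idx == 1)
  # number of series reaching headful k, against the closed-form survival
  reach_k <- vapply(1:7, function(k) sum(idx == k), 0L)
  pmf <- series_length_pmf(q, 7)
  surv <- rev(cumsum(rev(pmf)))        # P(length >= k)
  for (k in 1:7) {
    p <- surv[k]
    se <- sqrt(p * (1 - p) / n_series)
    expect_lt(abs(reach_k[k] / n_series - p), max(3 * se, 1e-9))
  }
  expect_equal(sum(series_length_pmf(0.5, 7)), 1)
  expect_equal(sum(series_length_pmf(1, 12)), 1)
})

test_that("the per-headful profile decays as q^(k-1)", {
  sys <- sim_system()
  q <- 0.7
  params <- simulation_params(n_donors = 2000, particles_per_donor = 10,
                              p_in_situ = 1, series_continuation = q,
                              recombination_prob = 1, seed = 23)
  lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
  out <- simulate_transduction(lys, sys$genome$loci, params)
  prof <- estimate_headful_profile(out)
  expect_equal(prof$hf, 1:7)
  n_series <- lys$n_series
  for (k in 1:7) {
    p <- q^(k - 1)
    se <- sqrt(p * (1 - p) / n_series)
    expect_lt(abs(prof$events[k] / n_series - p), max(3 * se, 1e-9))
  }
  # q = 1 gives a flat profile
  pf <- simulation_params(n_donors = 500, particles_per_donor = 10,
                          p_in_situ = 1, series_continuation = 1,
                          recombination_prob = 1, seed = 29)
  lysf <- simulate_lysate(sys$genome, sys$site, sys$model, pf)
  proff <- estimate_headful_profile(
    simulate_transduction(lysf, sys$genome$loci, pf))
  expect_true(all(proff$events == proff$events[1]))
  expect_true(attr(proff, "monotone"))
})

test_that("profile estimation validates its markers", {
  sys <- sim_system()
  params <- simulation_params(n_donors = 100, p_in_situ = 1, seed = 31)
  lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
  dup <- c(sys$genome$loci[1], sys$genome$loci[1])
  dup[[2]]$locus_id <- "mk1b"
  expect_error(estimate_headful_profile(
    simulate_transduction(lys, dup, params)), "distinct headful")
})

test_that("continuation probability is recovered from profiles", {
  # noiseless analytic profile: exact recovery
  exact <- data.frame(hf = 1:7, events = 0.5^(0:6))
  expect_equal(recover_continuation_probability(exact)$q_hat, 0.5,
               tolerance = 1e-9)
  # flat profile sits at the q = 1 boundary
  flat <- data.frame(hf = 1:7, events = rep(10, 7))
  expect_equal(recover_continuation_probability(flat)$q_hat, 1)
  # all-zero profile is degenerate
  expect_error(recover_continuation_probability(
    data.frame(hf = 1:7, events = rep(0, 7))), "degenerate")
  # simulated profile: estimate within 3 SE of the truth
  sys <- sim_system()
  q <- 0.7
  params <- simulation_params(n_donors = 2000, particles_per_donor = 10,
                              p_in_situ = 1, series_continuation = q,
                              recombination_prob = 1, seed = 37)
  lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
  prof <- estimate_headful_profile(
    simulate_transduction(lys, sys$genome$loci, params))
  fit <- recover_continuation_probability(prof)
  expect_lt(abs(fit$q_hat - q), 3 * fit$se)
})

test_that("in-situ packaging dominates pseudo-pac generalised transduction", {
  sys <- sim_system()
  params <- simulation_params(
    n_donors = 5000, particles_per_donor = 50, p_in_situ = 0.2,
    series_continuation = 0.55, recombination_prob = 1,
    ppac_sites = data.frame(position = sys$site$position,
                            direction = 1, relative_efficiency = 1e-4),
    seed = 41)
  lys <- simulate_lysate(sys$genome, sys$site, sys$model, params)
  out <- simulate_transduction(lys, sys$genome$loci[1], params)
  pm <- out$per_marker
  expect_gt(pm$freq_gt, 0)
  expect_gte(pm$freq_lt / pm$freq_gt, 100)
})
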