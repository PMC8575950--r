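test_that("directed distance matches a base-by-base walk", {
  expect_equal(directed_distance(100, 100, 1, 1000), 0)
  expect_equal(directed_distance(100, 100, -1, 1000), 0)
  expect_equal(directed_distance(100, 50, 1, 1000), 950)
  expect_equal(directed_distance(100, 50, -1, 1000), 50)
  # brute-force walk oracle on random cases
  set.seed(21)
  L <- 500
  for (i in 1:30) {
    a <- sample(0:(L - 1), 1); b <- sample(0:(L - 1), 1)
    d <- sample(c(1, -1), 1)
    walk <- 0; p <- a
    while (p != b) { p <- (p + d) %% L; walk <- walk + 1 }
    expect_equal(directed_distance(a, b, d, L), walk)
  }
  expect_error(directed_distance(-1, 5, 1, 10), "\\[0, L\\)")
})

test_that("distances in a fixed direction are complementary around the circle", {
  set.seed(22)
  for (i in 1:50) {
    L <- sample(100:10000, 1)
    a <- sample(0:(L - 1), 1); b <- sample(0:(L - 1), 1)
    d <- sample(c(1, -1), 1)
    s <- directed_distance(a, b, d, L) + directed_distance(b, a, d, L)
    expect_true(s %in% c(0, L))
  }
})

test_that("headful index counts full headfuls from the attB", {
  model <- builtin_prophage_models()$`80alpha`
  L <- 3e6
  site <- attb_site("Sa7", 1e6, 1)
  expect_equal(headful_index(site, 1e6, model, L), 1L)      # at the attB
  # marker inserted 35 kb downstream of the attB lands in the first headful
  expect_equal(headful_index(site, 1e6 + 35000, model, L), 1L)
  expect_equal(headful_index(site, 1e6 + 100000, model, L), 3L)
  # beyond 7 headfuls: out of reach
  expect_true(is.na(headful_index(site, 1e6 + 7 * 45000 + 1, model, L)))
  # minus-strand packaging walks the other way
  site_m <- attb_site("Sa5", 1e6, -1)
  expect_equal(headful_index(site_m, 1e6 - 100000, model, L), 3L)
})

test_that("headful index is non-decreasing and increments at multiples of H", {
  model <- prophage_model("toy", 1500, 5)
  L <- 20000
  site <- attb_site("s", 3000, 1)
  d <- 0:(5 * 1500 - 1)
  idx <- headful_index(site, (3000 + d) %% L, model, L)
  expect_true(all(diff(idx) >= 0))
  expect_equal(idx, as.integer(d %/% 1500) + 1L)
  # brute-force per-base oracle agreement
  oracle <- oracle_per_base_hf(site, model, L)
  pos <- (3000 + d) %% L
  expect_equal(idx, oracle[pos + 1])
})

test_that("headful windows tile the reach with no gap or overlap", {
  # single-window model
  m1 <- prophage_model("one", 5000, 1)
  w1 <- headful_windows(attb_site("s", 100, 1), m1, 50000)
  expect_length(w1, 1)
  expect_equal(w1$HF1$start, 100)
  expect_equal(w1$HF1$length, 5000)
  # the 80alpha geometry spans 315 kb in 7 windows
  m80 <- builtin_prophage_models()$`80alpha`
  w80 <- headful_windows(attb_site("Sa6", 2e6, 1), m80, 3e6)
  expect_length(w80, 7)
  expect_equal(sum(vapply(w80, `[[`, 0, "length")), 315000)
  # per-base marking oracle: every base of the reach in exactly one window
  set.seed(31)
  for (i in 1:10) {
    L <- sample(20000:100000, 1)
    model <- prophage_model("t", sample(1000:5000, 1), sample(2:6, 1))
    site <- attb_site("s", sample(0:(L - 1), 1), sample(c(1, -1), 1))
    wins <- headful_windows(site, model, L)
    marks <- rep(0L, L)
    for (w in wins) {
      pos <- (w$start + seq_len(w$length) - 1) %% L
      marks[pos + 1] <- marks[pos + 1] + 1L
    }
    oracle <- oracle_per_base_hf(site, model, L)
    expect_equal(marks == 1L, !is.na(oracle))
    expect_true(all(marks <= 1L))
  }
})

test_that("single-prophage LT reach is headful size times processive headfuls", {
  models <- builtin_prophage_models()
  expect_equal(lt_reach_span(models$`80alpha`), 315000)
  expect_equal(lt_reach_span(models$P22), 516000)
  expect_error(prophage_model("bad", 45000, 0), "max_headfuls")
})

test_that("poly-lysogen coverage equals per-base marking", {
  m80 <- builtin_prophage_models()$`80alpha`
  # single site on a 1 Mb genome: 315 kb reach = 31.5%
  cov1 <- polylysogen_coverage(1e6, list(attb_site("a", 0, 1)), m80)
  expect_equal(cov1$covered_bp, 315000)
  expect_equal(cov1$fraction, 0.315)
  # two sites overlapping by exactly one headful: union = 2*reach - H
  toy <- prophage_model("t", 1000, 4)   # reach 4000
  s1 <- attb_site("a", 0, 1)
  s2 <- attb_site("b", 3000, 1)         # windows 4 of a == window 1 of b
  cov2 <- polylysogen_coverage(100000, list(s1, s2), toy)
  expect_equal(cov2$covered_bp, 2 * 4000 - 1000)
  expect_equal(cov2$covered_bp, oracle_coverage(100000, list(s1, s2), toy))
  # saturation: reaches jointly exceeding the circle give fraction 1
  cov3 <- polylysogen_coverage(5000, list(attb_site("a", 0, 1),
                                          attb_site("b", 2500, -1)), toy)
  expect_equal(cov3$fraction, 1.0)
  expect_error(polylysogen_coverage(1e5, list(attb_site("a", 1, 1),
                                              attb_site("a", 2, 1)), toy),
               "duplicate")
})

test_that("coverage is monotone in sites and additive when disjoint", {
  toy <- prophage_model("t", 2000, 3)
  set.seed(41)
  for (i in 1:10) {
    L <- 80000
    sites <- lapply(1:4, function(k)
      attb_site(paste0("s", k), sample(0:(L - 1), 1), sample(c(1, -1), 1)))
    prev <- 0
    for (k in 1:4) {
      cov <- polylysogen_coverage(L, sites[1:k], toy)
      expect_gte(cov$covered_bp, prev)
      prev <- cov$covered_bp
    }
  }
  # disjoint reaches are additive
  s1 <- attb_site("a", 0, 1); s2 <- attb_site("b", 40000, 1)
  both <- polylysogen_coverage(80000, list(s1, s2), toy)
  expect_equal(both$covered_bp,
               polylysogen_coverage(80000, list(s1), toy)$covered_bp +
               polylysogen_coverage(80000, list(s2), toy)$covered_bp)
})

test_that("reversing the packaging direction mirrors the reach", {
  toy <- prophage_model("t", 1500, 4)
  set.seed(43)
  for (i in 1:10) {
    L <- 30000
    p <- sample(0:(L - 1), 1)
    fwd <- oracle_per_base_hf(attb_site("s", p, 1), toy, L)
    rev <- oracle_per_base_hf(attb_site("s", p, -1), toy, L)
    fwd_pos <- which(!is.na(fwd)) - 1
    rev_pos <- which(!is.na(rev)) - 1
    # mirror about the attB (half-open edge shifts by one base)
    expect_setequal((2 * p - 1 - fwd_pos) %% L, rev_pos)
    cov_f <- polylysogen_coverage(L, list(attb_site("s", p, 1)), toy)
    cov_r <- polylysogen_coverage(L, list(attb_site("s", p, -1)), toy)
    expect_equal(cov_f$covered_bp, cov_r$covered_bp)
    expect_setequal(rev_pos, {
      iv <- cov_r$per_site_reach$s
      ((iv$start + seq_len(iv$length) - 1) %% L)
    })
  }
})

test_that("locus compatibility reports the headful range of both edges", {
  toy <- prophage_model("t", 1000, 6)
  L <- 50000
  site <- attb_site("s", 10000, 1)
  inside3 <- genomic_locus("in3", circular_interval(12200, 400, L))
  straddle56 <- genomic_locus("x56", circular_interval(14900, 400, L))
  away <- genomic_locus("far", circular_interval(40000, 500, L))
  tab <- locus_compatibility_table(list(inside3, straddle56, away),
                                   list(site), toy, L)
  expect_equal(tab$s, c("HF 3", "HF 5-6", NA))
  # random loci and sites against the per-base oracle
  set.seed(47)
  for (i in 1:15) {
    L <- 2e6
    model <- prophage_model("t", 45000, 7)
    sites <- lapply(1:3, function(k)
      attb_site(paste0("s", k), sample(0:(L - 1), 1), sample(c(1, -1), 1)))
    loci <- lapply(1:5, function(k)
      genomic_locus(paste0("l", k),
                    circular_interval(sample(0:(L - 1), 1),
                                      sample(500:60000, 1), L)))
    tab <- locus_compatibility_table(loci, sites, model, L)
    for (j in 1:3) {
      want <- vapply(loci, oracle_locus_hf_range, "", site = sites[[j]],
                     model = model, L = L)
      expect_equal(tab[[paste0("s", j)]], want)
    }
  }
})
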