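# Stochastic simulator of the headful-packaging transduction mechanism:
# prophage induction, in-situ processive packaging (lateral transduction),
# ppac-initiated generalised transduction, and lytic phage production.
#
# Series-length law: a packaging series produces 1 + Geometric(q) headfuls,
# truncated at n_max, where q is the per-headful continuation probability.
# Under this law P(series length >= k) = q^(k-1) for k <= n_max, so the
# expected per-headful transfer profile decays geometrically with headful
# index. This one-parameter law is a modelling choice: the simplest decaying
# mechanism consistent with observed per-headful frequency declines.

#' Simulation parameters
#'
#' @param n_donors number of donor cells simulated.
#' @param induction_fraction probability a donor is induced (mitomycin C
#'   induction is near-complete; default 1).
#' @param p_in_situ probability a packaging series initiates on a
#'   still-integrated prophage (an LT series) rather than an excised circle
#'   (lytic phage production).
#' @param series_continuation q, the probability each additional processive
#'   headful is packaged; series length is 1 + Geometric(q) truncated at the
#'   model's \code{max_headfuls}.
#' @param ppac_sites data.frame of pseudo-pac sites with columns
#'   \code{position}, \code{direction} (+1/-1) and
#'   \code{relative_efficiency} in [0, 1] (chromosomal pac mimics are
#'   recognised orders of magnitude less efficiently than the true pac;
#'   ~1e-4 is typical). NULL for none.
#' @param recombination_prob probability a delivered chromosomal fragment
#'   recombines into the recipient chromosome.
#' @param lysogenisation_prob probability an infecting phage particle
#'   lysogenises its recipient.
#' @param particles_per_donor packaging series initiated per induced donor
#'   (abstracts the in-situ replication that amplifies packaging substrate).
#' @param seed integer seed; every simulator draw derives from it.
#' @return an object of class \code{simulation_params}.
#' @export
simulation_params <- function(n_donors = 1000, induction_fraction = 1,
                              p_in_situ = 0.2, series_continuation = 0.55,
                              ppac_sites = NULL, recombination_prob = 0.005,
                              lysogenisation_prob = 0.02,
                              particles_per_donor = 50, seed = 1L) {
  probs <- c(induction_fraction, p_in_situ, series_continuation,
             recombination_prob, lysogenisation_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    ltm_stop("all probabilities must lie in [0, 1]")
  if (n_donors < 1 || particles_per_donor < 1)
    ltm_stop("counts must be positive")
  if (!is.null(ppac_sites)) {
    need <- c("position", "direction", "relative_efficiency")
    if (!is.data.frame(ppac_sites) || !all(need %in% names(ppac_sites)))
      ltm_stop("ppac_sites needs columns %s", paste(need, collapse = ", "))
    if (any(ppac_sites$relative_efficiency < 0 |
            ppac_sites$relative_efficiency > 1))
      ltm_stop("ppac relative_efficiency must lie in [0, 1]")
    if (!all(ppac_sites$direction %in% c(1, -1)))
      ltm_stop("ppac direction must be +1 or -1")
  }
  structure(list(n_donors = as.integer(n_donors),
                 induction_fraction = induction_fraction,
                 p_in_situ = p_in_situ,
                 series_continuation = series_continuation,
                 ppac_sites = ppac_sites,
                 recombination_prob = recombination_prob,
                 lysogenisation_prob = lysogenisation_prob,
                 particles_per_donor = as.integer(particles_per_donor),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

# series lengths: 1 + Geometric(q), truncated at n_max
draw_series_lengths <- function(n, q, n_max) {
  if (n == 0) return(integer())
  if (q >= 1) return(rep(as.integer(n_max), n))
  if (q <= 0) return(rep(1L, n))
  pmin(1L + stats::rgeom(n, prob = 1 - q), as.integer(n_max))
}

#' Closed-form truncated-geometric series-length law
#'
#' P(length = k) for k in 1..n_max under the simulator's series-length model:
#' \code{q^(k-1) (1-q)} for k < n_max and \code{q^(n_max-1)} at the
#' truncation point.
#'
#' @param q continuation probability.
#' @param n_max truncation point.
#' @return numeric vector of length \code{n_max}, summing to 1.
#' @export
series_length_pmf <- function(q, n_max) {
  k <- seq_len(n_max)
  p <- q^(k - 1) * (1 - q)
  p[n_max] <- q^(n_max - 1)
  p
}

#' Simulate a transducing lysate
#'
#' For every induced donor, \code{particles_per_donor} packaging series are
#' initiated. With probability \code{p_in_situ} a series starts at the pac
#' site of the still-integrated prophage and packages consecutive headful
#' windows of chromosome (an LT series; the first headful carries
#' \code{hf1_phage_carryover} bp of phage DNA). Otherwise the series packages
#' phage genomes (lytic production). Independently, each pseudo-pac site
#' initiates generalised-transduction series at its relative efficiency,
#' packaging consecutive headfuls from its own position. Series lengths
#' follow the truncated-geometric law ([series_length_pmf()]). Fully
#' reproducible for a given seed.
#'
#' @param genome an [annotated_genome()] (only its length is required).
#' @param site the occupied [attb_site()]; must be in the genome's registry
#'   if one is present.
#' @param model a [prophage_model()].
#' @param params a [simulation_params()].
#' @return an object of class \code{lt_lysate}: a particle table (columns
#'   \code{mode} phage/LT/GT, \code{origin}, \code{dir}, \code{series_index},
#'   \code{off_lo}, \code{off_hi} = directed offsets of the chromosomal
#'   content) plus the inputs.
#' @export
simulate_lysate <- function(genome, site, model, params) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(site, "attb_site"),
            inherits(model, "prophage_model"),
            inherits(params, "simulation_params"))
  if (length(genome$attb_sites)) {
    ids <- vapply(genome$attb_sites, `[[`, "", "site_id")
    if (!site$site_id %in% ids)
      ltm_stop("site '%s' is not in the genome's attB registry", site$site_id)
  }
  if (site$position >= genome$length)
    ltm_stop("attB position beyond genome end")
  L <- genome$length
  H <- model$headful_size
  n_max <- model$max_headfuls
  q <- params$series_continuation
  set.seed(params$seed)

  n_induced <- stats::rbinom(1, params$n_donors, params$induction_fraction)
  n_slots <- n_induced * params$particles_per_donor
  n_lt <- stats::rbinom(1, n_slots, params$p_in_situ)
  n_lytic <- n_slots - n_lt

  blocks <- list()
  if (n_lt > 0) {
    len <- draw_series_lengths(n_lt, q, n_max)
    hf <- sequence(len)
    off_lo <- (hf - 1) * H
    off_lo[hf == 1] <- model$hf1_phage_carryover
    blocks$lt <- data.frame(mode = "LT",
                            origin = packaging_origin(site, model, L),
                            dir = site$direction, series_index = hf,
                            off_lo = off_lo, off_hi = hf * H)
  }
  if (n_lytic > 0) {
    len <- draw_series_lengths(n_lytic, q, n_max)
    hf <- sequence(len)
    blocks$phage <- data.frame(mode = "phage", origin = site$position,
                               dir = site$direction, series_index = hf,
                               off_lo = NA_real_, off_hi = NA_real_)
  }
  if (!is.null(params$ppac_sites) && nrow(params$ppac_sites)) {
    for (j in seq_len(nrow(params$ppac_sites))) {
      pp <- params$ppac_sites[j, ]
      n_gt <- stats::rbinom(1, n_slots, pp$relative_efficiency)
      if (n_gt == 0) next
      len <- draw_series_lengths(n_gt, q, n_max)
      hf <- sequence(len)
      blocks[[paste0("gt", j)]] <- data.frame(
        mode = "GT", origin = pp$position %% L, dir = pp$direction,
        series_index = hf, off_lo = (hf - 1) * H, off_hi = hf * H)
    }
  }
  particles <- if (length(blocks)) do.call(rbind, blocks)
               else data.frame(mode = character(), origin = numeric(),
                               dir = integer(), series_index = integer(),
                               off_lo = numeric(), off_hi = numeric())
  rownames(particles) <- NULL
  structure(list(particles = particles, genome_length = L, site = site,
                 model = model, params = params,
                 n_induced = n_induced, n_series = n_slots),
            class = "lt_lysate")
}

#' @export
print.lt_lysate <- function(x, ...) {
  tab <- table(x$particles$mode)
  cat(sprintf("<lt_lysate> %d particles from %d induced donors (%s)\n",
              nrow(x$particles), x$n_induced,
              paste(sprintf("%s:%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# directed offset of position m from origin along dir
directed_offset <- function(m, origin, dir, L) {
  ifelse(dir == 1, (m - origin) %% L, (origin - m) %% L)
}

#' Simulate transduction of chromosomal markers from a lysate
#'
#' A marker transfers when a particle's packaged chromosomal interval fully
#' contains its span and a Bernoulli(recombination_prob) recombination
#' succeeds. Phage particles lysogenise recipients with probability
#' \code{lysogenisation_prob}. Frequencies are normalised per donor cell.
#'
#' @param lysate an [simulate_lysate()] result.
#' @param markers list of [genomic_locus()]s on the donor genome.
#' @param params a [simulation_params()]; defaults to the lysate's. The
#'   recipient-side draws use a seed derived from it (seed + 1), so a fixed
#'   seed fixes the whole experiment.
#' @return an object of class \code{transduction_outcome}: \code{per_marker}
#'   data.frame (containment counts, transfer events and TE/donor frequencies
#'   overall and split by LT/GT), \code{lysogens_per_donor}, and the inputs.
#' @export
simulate_transduction <- function(lysate, markers, params = lysate$params) {
  stopifnot(inherits(lysate, "lt_lysate"))
  L <- lysate$genome_length
  pt <- lysate$particles
  set.seed(params$seed + 1L)
  chrom <- pt[pt$mode != "phage", , drop = FALSE]
  rows <- lapply(markers, function(mk) {
    stopifnot(inherits(mk, "genomic_locus"))
    m <- mk$span$start
    len <- mk$span$length
    # directed offset of the marker's packaging-proximal edge
    u <- ifelse(chrom$dir == 1, (m - chrom$origin) %% L,
                (chrom$origin - m - len) %% L)
    contained <- u >= chrom$off_lo & (u + len) <= chrom$off_hi
    n_lt <- sum(contained & chrom$mode == "LT")
    n_gt <- sum(contained & chrom$mode == "GT")
    ev_lt <- stats::rbinom(1, n_lt, params$recombination_prob)
    ev_gt <- stats::rbinom(1, n_gt, params$recombination_prob)
    data.frame(marker_id = mk$locus_id,
               hf_index = headful_index(lysate$site, m, lysate$model, L),
               contained_lt = n_lt, contained_gt = n_gt,
               events_lt = ev_lt, events_gt = ev_gt,
               events = ev_lt + ev_gt,
               freq_lt = ev_lt / params$n_donors,
               freq_gt = ev_gt / params$n_donors,
               frequency = (ev_lt + ev_gt) / params$n_donors,
               stringsAsFactors = FALSE)
  })
  per_marker <- if (length(rows)) do.call(rbind, rows) else NULL
  n_phage <- sum(pt$mode == "phage")
  lys <- stats::rbinom(1, n_phage, params$lysogenisation_prob)
  structure(list(per_marker = per_marker,
                 lysogens_per_donor = lys / params$n_donors,
                 n_phage_particles = n_phage,
                 n_donors = params$n_donors, n_series = lysate$n_series,
                 site = lysate$site, model = lysate$model, params = params),
            class = "transduction_outcome")
}

#' Per-headful transfer profile
#'
#' Orders per-marker LT transfer frequencies by headful index. Requires the
#' markers to occupy distinct headful windows (one marker per headful).
#'
#' @param outcome a [simulate_transduction()] result.
#' @return data.frame of class \code{headful_profile} with columns \code{hf},
#'   \code{events} and \code{frequency}; attribute \code{monotone} flags
#'   whether the empirical profile is non-increasing.
#' @export
estimate_headful_profile <- function(outcome) {
  stopifnot(inherits(outcome, "transduction_outcome"))
  pm <- outcome$per_marker
  if (is.null(pm) || !nrow(pm)) ltm_stop("outcome has no marker data")
  if (any(is.na(pm$hf_index)))
    ltm_stop("marker(s) out of LT reach of the attB site")
  if (anyDuplicated(pm$hf_index))
    ltm_stop("markers must cover distinct headful windows")
  prof <- data.frame(hf = pm$hf_index, events = pm$events_lt,
                     frequency = pm$freq_lt)
  prof <- prof[order(prof$hf), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "monotone") <- !is.unsorted(rev(prof$frequency))
  class(prof) <- c("headful_profile", "data.frame")
  prof
}

#' Recover the series continuation probability from a headful profile
#'
#' Maximum-likelihood estimate of q under the truncated-geometric
#' series-length law. Conditional on a marker transfer having occurred, the
#' probability it happened at headful k is q^(k-1) / sum_j q^(j-1)
#' (the per-fragment detection probability cancels), so q is estimated from
#' the multinomial likelihood of the per-headful event counts. The standard
#' error comes from the observed information at the optimum.
#'
#' @param profile a [estimate_headful_profile()] result, or any data.frame
#'   with columns \code{hf} and \code{events} (non-integer weights, e.g. an
#'   exact analytic profile, are accepted).
#' @param n_max truncation point; defaults to \code{max(profile$hf)}.
#' @return list with \code{q_hat} and \code{se} (NA at the q = 1 boundary).
#' @export
recover_continuation_probability <- function(profile,
                                             n_max = max(profile$hf)) {
  if (!all(c("hf", "events") %in% names(profile)))
    ltm_stop("profile needs columns hf and events")
  w <- profile$events
  k <- profile$hf
  if (sum(w) <= 0) ltm_stop("degenerate profile: no transfer events")
  N <- sum(w)
  M <- sum(w * (k - 1))
  K <- as.integer(n_max)
  if (K < 2) ltm_stop("need n_max >= 2")
  S  <- function(q) sum(q^(0:(K - 1)))
  S1 <- function(q) sum((1:(K - 1)) * q^(0:(K - 2)))
  S2 <- function(q) if (K < 3) 0 else
    sum((2:(K - 1)) * (1:(K - 2)) * q^(0:(K - 3)))
  score <- function(q) M / q - N * S1(q) / S(q)
  # boundaries: all mass at HF1 -> q = 0; mean offset >= flat mean -> q = 1
  if (M == 0) return(list(q_hat = 0, se = NA_real_))
  if (M / N >= (K - 1) / 2) return(list(q_hat = 1, se = NA_real_))
  q_hat <- stats::uniroot(score, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  obs_info <- M / q_hat^2 +
    N * (S2(q_hat) * S(q_hat) - S1(q_hat)^2) / S(q_hat)^2
  list(q_hat = q_hat, se = if (obs_info > 0) 1 / sqrt(obs_info) else NA_real_)
}
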