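# Circular-chromosome headful geometry: attB-anchored headful windows,
# locus-to-headful assignment, LT reach and poly-lysogen coverage.
#
# Convention: 0-based, half-open intervals [start, start + length) with
# wrap-around modulo the genome length L; packaging direction is +1
# (increasing coordinate) or -1 (decreasing).

#' Circular genomic interval
#'
#' @param start 0-based start position in \code{[0, L)}.
#' @param length interval length in bp, \code{0 < length <= L}.
#' @param L genome length in bp.
#' @return an object of class \code{circular_interval}.
#' @export
circular_interval <- function(start, length, L) {
  if (!is.numeric(L) || L <= 0) ltm_stop("genome length L must be positive")
  if (!is.numeric(start) || start < 0 || start >= L)
    ltm_stop("start must lie in [0, L)")
  if (!is.numeric(length) || length <= 0 || length > L)
    ltm_stop("length must satisfy 0 < length <= L")
  structure(list(start = start, length = length, L = L),
            class = "circular_interval")
}

#' Does a circular interval contain a position?
#'
#' @param interval a [circular_interval()].
#' @param pos position(s) in \code{[0, L)}.
#' @return logical vector.
#' @export
interval_contains <- function(interval, pos) {
  stopifnot(inherits(interval, "circular_interval"))
  ((pos - interval$start) %% interval$L) < interval$length
}

# split a circular interval into 1-2 linear [start, end) pieces
linear_pieces <- function(start, length, L) {
  end <- start + length
  if (end <= L) list(c(start, end))
  else list(c(start, L), c(0, end - L))
}

# total overlap (bp) between two circular intervals on the same genome
circular_overlap <- function(a_start, a_len, b_start, b_len, L) {
  pa <- linear_pieces(a_start %% L, a_len, L)
  pb <- linear_pieces(b_start %% L, b_len, L)
  tot <- 0
  for (x in pa) for (y in pb)
    tot <- tot + max(0, min(x[2], y[2]) - max(x[1], y[1]))
  tot
}

#' Prophage attachment (attB) site
#'
#' The chromosomal position where a temperate phage integrates; its position
#' and packaging direction anchor the in-situ headful packaging series of
#' lateral transduction.
#'
#' @param site_id site label (e.g. "Sa6", "St4").
#' @param position 0-based position in \code{[0, L)} (validated against L at
#'   use time).
#' @param direction +1 (packaging toward increasing coordinates) or -1.
#' @param occupied prophage id integrated at the site, or NA.
#' @return an object of class \code{attb_site}.
#' @export
attb_site <- function(site_id, position, direction, occupied = NA_character_) {
  if (!direction %in% c(1, -1)) ltm_stop("direction must be +1 or -1")
  if (!is.numeric(position) || position < 0)
    ltm_stop("position must be a non-negative coordinate")
  structure(list(site_id = as.character(site_id), position = position,
                 direction = as.integer(direction),
                 occupied = occupied),
            class = "attb_site")
}

#' Prophage headful-packaging model
#'
#' @param phage_id phage label.
#' @param headful_size capsid capacity H in bp (~45 kb for staphylococcal
#'   80alpha/phi11, ~43 kb for P22).
#' @param max_headfuls maximum number of processive headfuls n_max (7
#'   demonstrated for 80alpha, 12 for P22).
#' @param prophage_length integrated prophage length in bp, or NA.
#' @param pac_offset bp from the attB to the embedded pac site along the
#'   packaging direction. Headful indices in published tables are measured
#'   from the attB itself, so the default is 0; set it to shift the packaging
#'   origin to the physical pac position.
#' @param hf1_phage_carryover bp of phage DNA packaged at the start of the
#'   first headful during lateral transduction (reduces the chromosomal
#'   content of HF1); \code{0 <= carryover < H}.
#' @return an object of class \code{prophage_model}.
#' @export
prophage_model <- function(phage_id, headful_size, max_headfuls,
                           prophage_length = NA_real_, pac_offset = 0,
                           hf1_phage_carryover = 0) {
  if (!is.numeric(headful_size) || headful_size <= 0)
    ltm_stop("headful_size must be > 0")
  if (!is.numeric(max_headfuls) || max_headfuls < 1 ||
      max_headfuls != round(max_headfuls))
    ltm_stop("max_headfuls must be an integer >= 1")
  if (hf1_phage_carryover < 0 || hf1_phage_carryover >= headful_size)
    ltm_stop("need 0 <= hf1_phage_carryover < headful_size")
  structure(list(phage_id = as.character(phage_id),
                 headful_size = headful_size,
                 max_headfuls = as.integer(max_headfuls),
                 prophage_length = prophage_length,
                 pac_offset = pac_offset,
                 hf1_phage_carryover = hf1_phage_carryover),
            class = "prophage_model")
}

#' Built-in prophage packaging models
#'
#' The two demonstrated lateral-transduction systems: staphylococcal phage
#' 80alpha (headful ~45 kb, processive packaging demonstrated to 7 headfuls)
#' and Salmonella phage P22 (headful ~43 kb, demonstrated to 12 headfuls).
#' phi11 shares the 80alpha capsid geometry.
#'
#' @return named list of [prophage_model()] objects
#'   (\code{"80alpha"}, \code{"P22"}, \code{"phi11"}).
#' @export
builtin_prophage_models <- function() {
  list(
    `80alpha` = prophage_model("80alpha", 45000, 7),
    P22       = prophage_model("P22", 43000, 12),
    phi11     = prophage_model("phi11", 45000, 7)
  )
}

#' Genomic locus on a circular chromosome
#'
#' @param locus_id locus label (e.g. "vSaalpha", "SPI-2", a resistance
#'   marker).
#' @param span a [circular_interval()].
#' @param locus_class free-text class (virulence island, marker, ...).
#' @return an object of class \code{genomic_locus}.
#' @export
genomic_locus <- function(locus_id, span, locus_class = "") {
  stopifnot(inherits(span, "circular_interval"))
  structure(list(locus_id = as.character(locus_id), span = span,
                 locus_class = as.character(locus_class)),
            class = "genomic_locus")
}

#' Directed distance on a circular genome
#'
#' Number of bases walked from \code{from_pos} to reach \code{to_pos} moving
#' in \code{direction}, modulo L. Satisfies
#' \code{directed_distance(a,b,d,L) + directed_distance(b,a,d,L)} being 0
#' (coincident) or L.
#'
#' @param from_pos,to_pos positions in \code{[0, L)}; vectorised.
#' @param direction +1 or -1.
#' @param L genome length.
#' @return distance(s) in \code{[0, L)}.
#' @export
directed_distance <- function(from_pos, to_pos, direction, L) {
  if (!all(direction %in% c(1, -1))) ltm_stop("direction must be +1 or -1")
  if (any(from_pos < 0 | from_pos >= L | to_pos < 0 | to_pos >= L))
    ltm_stop("positions must lie in [0, L)")
  (direction * (to_pos - from_pos)) %% L
}

# packaging origin of a site under a model (attB shifted by pac_offset)
packaging_origin <- function(site, model, L) {
  (site$position + site$direction * model$pac_offset) %% L
}

#' Headful index of a locus position relative to an attB site
#'
#' The headful unit in which a position would be packaged during lateral
#' transduction from a prophage at \code{site}:
#' \code{floor(directed_distance / H) + 1}. Positions farther than
#' \code{max_headfuls} headfuls are out of reach (NA).
#'
#' @param site an [attb_site()].
#' @param locus_pos position(s) in \code{[0, L)}.
#' @param model a [prophage_model()].
#' @param L genome length in bp.
#' @return integer headful index (>= 1), NA when out of reach; vectorised
#'   over \code{locus_pos}.
#' @export
headful_index <- function(site, locus_pos, model, L) {
  stopifnot(inherits(site, "attb_site"), inherits(model, "prophage_model"))
  d <- directed_distance(packaging_origin(site, model, L), locus_pos,
                         site$direction, L)
  n <- as.integer(d %/% model$headful_size) + 1L
  n[n > model$max_headfuls] <- NA_integer_
  n
}

#' Headful windows of a prophage from its attB site
#'
#' Window k spans directed offsets \code{[(k-1) H, k H)} from the packaging
#' origin along the packaging direction: consecutive, disjoint intervals of
#' length H that tile the LT reach. A reach exceeding the full circle is
#' truncated at L with a warning.
#'
#' @inheritParams headful_index
#' @return named list (\code{HF1}, \code{HF2}, ...) of
#'   [circular_interval()]s.
#' @export
headful_windows <- function(site, model, L) {
  stopifnot(inherits(site, "attb_site"), inherits(model, "prophage_model"))
  H <- model$headful_size
  n <- model$max_headfuls
  origin <- packaging_origin(site, model, L)
  if (n * H > L) {
    warning("reach exceeds the full circle; truncating at L")
    n <- ceiling(L / H)
  }
  out <- vector("list", n)
  for (k in seq_len(n)) {
    len <- min(H, L - (k - 1) * H)
    if (len <= 0) { out[[k]] <- NULL; next }
    start <- if (site$direction == 1) (origin + (k - 1) * H) %% L
             else (origin - (k - 1) * H - len) %% L
    out[[k]] <- circular_interval(start, len, L)
  }
  names(out) <- paste0("HF", seq_len(n))
  out[!vapply(out, is.null, TRUE)]
}

#' Maximal chromosomal span reachable by a single prophage via LT
#'
#' @param model a [prophage_model()].
#' @return reach in bp: \code{headful_size * max_headfuls} (315,000 for the
#'   built-in 80alpha model; 516,000 for P22).
#' @export
lt_reach_span <- function(model) {
  stopifnot(inherits(model, "prophage_model"))
  model$headful_size * model$max_headfuls
}

# the reach of one site as a single circular interval (truncated at L)
lt_reach_interval <- function(site, model, L) {
  span <- min(lt_reach_span(model), L)
  origin <- packaging_origin(site, model, L)
  start <- if (site$direction == 1) origin else (origin - span) %% L
  circular_interval(start, span, L)
}

#' Poly-lysogen LT coverage of a circular chromosome
#'
#' The union of the per-site LT reaches of several integrated prophages: the
#' chromosomal fraction mobilisable in a single induction event from a
#' poly-lysogenic strain.
#'
#' @param L genome length in bp.
#' @param sites list of [attb_site()]s (unique ids).
#' @param models a single [prophage_model()] applied to every site, or a
#'   named list keyed by site_id.
#' @return an object of class \code{coverage_summary}: \code{covered_bp},
#'   \code{genome_length}, \code{fraction} and \code{per_site_reach}.
#' @export
polylysogen_coverage <- function(L, sites, models) {
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(ids)) ltm_stop("duplicate site_id: %s",
                                   ids[duplicated(ids)][1])
  model_for <- function(id) {
    if (inherits(models, "prophage_model")) models
    else models[[id]] %||% ltm_stop("no prophage model for site '%s'", id)
  }
  reaches <- lapply(sites, function(s) lt_reach_interval(s, model_for(s$site_id), L))
  names(reaches) <- ids
  segs <- do.call(rbind, lapply(reaches, function(iv)
    do.call(rbind, lapply(linear_pieces(iv$start, iv$length, iv$L),
                          function(p) data.frame(start = p[1], end = p[2])))))
  covered <- if (is.null(segs) || !nrow(segs)) 0 else {
    ir <- IRanges::reduce(IRanges::IRanges(start = segs$start + 1,
                                           end = segs$end))
    sum(IRanges::width(ir))
  }
  structure(list(covered_bp = covered, genome_length = L,
                 fraction = covered / L, per_site_reach = reaches),
            class = "coverage_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("<coverage_summary> %d/%d bp covered (%.1f%%) from %d site(s)\n",
              x$covered_bp, x$genome_length, 100 * x$fraction,
              length(x$per_site_reach)))
  invisible(x)
}

#' Locus-to-headful compatibility table
#'
#' For every (locus, attB site) pair, the range of headful indices into which
#' the locus would be packaged by LT from that site: \code{"HF k"} when the
#' locus lies inside one window, \code{"HF k-m"} when it straddles window
#' boundaries, NA when fully out of reach. Both edges of the locus span are
#' used, not its midpoint.
#'
#' @param loci list of [genomic_locus()]s.
#' @param sites list of [attb_site()]s.
#' @param models a single [prophage_model()] or named list keyed by site_id.
#' @param L genome length in bp.
#' @return data.frame of class \code{hf_compatibility}: one row per locus,
#'   one character column per site (plus \code{locus_id}).
#' @export
locus_compatibility_table <- function(loci, sites, models, L) {
  ids <- vapply(sites, `[[`, "", "site_id")
  model_for <- function(id) {
    if (inherits(models, "prophage_model")) models else models[[id]]
  }
  cell <- function(locus, site) {
    model <- model_for(site$site_id)
    wins <- headful_windows(site, model, L)
    hit <- which(vapply(wins, function(w)
      circular_overlap(locus$span$start, locus$span$length,
                       w$start, w$length, L) > 0, TRUE))
    if (!length(hit)) return(NA_character_)
    k <- range(hit)
    if (k[1] == k[2]) sprintf("HF %d", k[1]) else
      sprintf("HF %d-%d", k[1], k[2])
  }
  out <- data.frame(locus_id = vapply(loci, `[[`, "", "locus_id"),
                    stringsAsFactors = FALSE)
  for (j in seq_along(sites))
    out[[ids[j]]] <- vapply(loci, cell, "", site = sites[[j]])
  class(out) <- c("hf_compatibility", "data.frame")
  out
}
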