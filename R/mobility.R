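# Mobility metrics: per-donor transfer frequencies, cargo capacity rates,
# relative frequency of genetic mobility, and the comparative ledger.

ltm_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' Donor calibration: optical-density landmark to donor CFU/ml
#'
#' Transduction and lysogenisation titres (TrU/ml) are converted to transfer
#' events per donor cell using the donor density at the moment of prophage
#' induction. Two calibrations are standard: *S. aureus* lysogens induced at
#' OD540 0.15 (6.5e7 CFU/ml) and *Salmonella* lysogens induced at OD600 0.20
#' (1.0e8 CFU/ml); see [builtin_calibrations()].
#'
#' @param organism_label free-text organism tag, used to match records.
#' @param od_landmark optical density at induction (dimensionless).
#' @param donor_cfu_per_ml donor cells per ml at that density; must be > 0.
#' @return an object of class \code{donor_calibration}.
#' @export
donor_calibration <- function(organism_label, od_landmark, donor_cfu_per_ml) {
  if (!is.numeric(donor_cfu_per_ml) || length(donor_cfu_per_ml) != 1 ||
      !is.finite(donor_cfu_per_ml) || donor_cfu_per_ml <= 0)
    ltm_stop("donor_cfu_per_ml must be a single positive number")
  structure(list(organism_label = as.character(organism_label),
                 od_landmark = as.numeric(od_landmark),
                 donor_cfu_per_ml = donor_cfu_per_ml),
            class = "donor_calibration")
}

#' The two packaged donor calibrations
#'
#' @return named list of [donor_calibration()] objects: \code{s_aureus}
#'   (OD540 0.15, 6.5e7 CFU/ml) and \code{salmonella} (OD600 0.20, 1e8 CFU/ml).
#' @export
builtin_calibrations <- function() {
  list(
    s_aureus   = donor_calibration("s_aureus",   0.15, 6.5e7),
    salmonella = donor_calibration("salmonella", 0.20, 1.0e8)
  )
}

#' Transfer frequency in transfer events per donor cell
#'
#' A point estimate or a closed interval (some literature values are reported
#' as ranges). Stored normalised with \code{lo <= hi}; a point value has
#' \code{lo == hi}.
#'
#' @param lo,hi non-negative endpoints in TE/donor; \code{hi} defaults to
#'   \code{lo}. Endpoints may be given in either order.
#' @return an object of class \code{transfer_frequency}.
#' @export
transfer_frequency <- function(lo, hi = lo) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1 || length(hi) != 1 ||
      is.na(lo) || is.na(hi) || lo < 0 || hi < 0)
    ltm_stop("transfer_frequency endpoints must be single non-negative numbers")
  ends <- sort(c(lo, hi))
  structure(list(lo = ends[1], hi = ends[2], is_range = ends[1] != ends[2]),
            class = "transfer_frequency")
}

#' @export
print.transfer_frequency <- function(x, ...) {
  cat("<transfer_frequency>", format_frequency(x), "TE/donor\n")
  invisible(x)
}

#' Cargo annotation: accessory and total ORF counts
#'
#' Counts may carry half units (an ORF truncated at a headful boundary counts
#' 0.5), so values like 17.5/51 or 41.5/41.5 are valid.
#'
#' @param accessory_orfs accessory ORFs utilisable by the recipient host
#'   (virulence factors, AMR genes, ...); non-negative, multiple of 0.5.
#' @param total_orfs total ORFs in the mobilised sequence; positive, multiple
#'   of 0.5, and \code{>= accessory_orfs}.
#' @return an object of class \code{cargo_annotation}.
#' @export
cargo_annotation <- function(accessory_orfs, total_orfs) {
  half_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
    isTRUE(all.equal(x * 2, round(x * 2)))
  if (!half_ok(accessory_orfs) || !half_ok(total_orfs))
    ltm_stop("ORF counts must be single numbers with 0.5 granularity")
  if (total_orfs <= 0) ltm_stop("total_orfs must be > 0")
  if (accessory_orfs < 0 || accessory_orfs > total_orfs)
    ltm_stop("need 0 <= accessory_orfs <= total_orfs (got %s/%s)",
             accessory_orfs, total_orfs)
  structure(list(accessory_orfs = accessory_orfs, total_orfs = total_orfs),
            class = "cargo_annotation")
}

# category -> allowed transfer mechanisms (as tabulated)
ltm_category_mechanisms <- list(
  plasmid                = c("conjugation", "mobilisation", "GT"),
  phage                  = "lysogenisation",
  PICI                   = "PICI_transfer",
  conjugative_transposon = "conjugation",
  chromosomal_marker     = c("GT", "LT")
)

#' A single mobility record: one genetic element or chromosomal marker
#'
#' @param element_id unique identifier.
#' @param category one of \code{plasmid}, \code{phage}, \code{PICI},
#'   \code{conjugative_transposon}, \code{chromosomal_marker}.
#' @param mechanism transfer mechanism, restricted per category (conjugation,
#'   mobilisation, lysogenisation, PICI_transfer, GT, LT).
#' @param frequency a [transfer_frequency()], or NULL if the record instead
#'   carries a raw titre.
#' @param cargo a [cargo_annotation()] or NA (not determined).
#' @param accession sequence accession, or "".
#' @param organism organism tag resolving to a donor calibration (needed only
#'   for titre-based records).
#' @param titre_tru_per_ml raw titre in TrU/ml, or NA.
#' @param source citation text.
#' @return an object of class \code{mobility_record}.
#' @export
mobility_record <- function(element_id, category, mechanism, frequency = NULL,
                            cargo = NA, accession = "", organism = "",
                            titre_tru_per_ml = NA_real_, source = "") {
  if (!category %in% names(ltm_category_mechanisms))
    ltm_stop("unknown category '%s'", category)
  if (!mechanism %in% ltm_category_mechanisms[[category]])
    ltm_stop("mechanism '%s' is not valid for category '%s'",
             mechanism, category)
  if (is.null(frequency) && is.na(titre_tru_per_ml))
    ltm_stop("record '%s': need a frequency or a titre", element_id)
  if (!is.null(frequency) && !inherits(frequency, "transfer_frequency"))
    ltm_stop("frequency must be a transfer_frequency")
  if (!(length(cargo) == 1 && is.na(cargo[1])) &&
      !inherits(cargo, "cargo_annotation"))
    ltm_stop("cargo must be a cargo_annotation or NA")
  structure(list(element_id = as.character(element_id),
                 accession = as.character(accession),
                 category = category, mechanism = mechanism,
                 organism = as.character(organism),
                 frequency = frequency, titre_tru_per_ml = titre_tru_per_ml,
                 cargo = cargo, source = as.character(source)),
            class = "mobility_record")
}

#' Normalise a transduction titre to transfer events per donor cell
#'
#' TE per donor cell = transductant units (TrU) per ml divided by donor
#' CFU per ml at the time of prophage induction.
#'
#' @param titre titre(s) in TrU/ml; non-negative.
#' @param calibration a [donor_calibration()].
#' @return TE/donor value(s), at full precision (render separately with
#'   [format_sci()]).
#' @examples
#' cal <- builtin_calibrations()$s_aureus
#' normalize_transfer_frequency(3.00e7, cal)   # 0.4615...
#' @export
normalize_transfer_frequency <- function(titre, calibration) {
  if (!inherits(calibration, "donor_calibration"))
    ltm_stop("calibration must be a donor_calibration")
  if (!is.numeric(titre) || any(is.na(titre)) || any(titre < 0))
    ltm_stop("titre must be non-negative (TrU/ml)")
  titre / calibration$donor_cfu_per_ml
}

#' Summarise replicate titres
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' independent replicate titres, as reported for repeated transduction
#' experiments.
#'
#' @param titres numeric vector of at least one non-negative titre.
#' @return list with \code{mean}, \code{sd} (NA for a single replicate, 0 for
#'   identical replicates) and \code{n}.
#' @export
summarize_replicates <- function(titres) {
  if (!is.numeric(titres) || length(titres) < 1 || any(is.na(titres)) ||
      any(titres < 0))
    ltm_stop("titres must be a non-empty vector of non-negative values")
  list(mean = mean(titres),
       sd = if (length(titres) > 1) stats::sd(titres) else NA_real_,
       n = length(titres))
}

#' Cargo capacity rate
#'
#' The fraction of the mobilised sequence that is usable by the recipient:
#' accessory ORFs / total ORFs, kept at full precision. Tables render it to
#' two decimals ([format_cargo_rate()]).
#'
#' @param cargo a [cargo_annotation()] or NA.
#' @return rate in (0, 1], or NA for not-determined cargo.
#' @examples
#' cargo_capacity_rate(cargo_annotation(4, 26))    # 0.1538...
#' @export
cargo_capacity_rate <- function(cargo) {
  if (length(cargo) == 1 && is.na(cargo[1])) return(NA_real_)
  if (!inherits(cargo, "cargo_annotation"))
    ltm_stop("cargo must be a cargo_annotation or NA")
  cargo$accessory_orfs / cargo$total_orfs
}

#' Relative frequency of genetic mobility
#'
#' Transfer frequency multiplied by the cargo capacity rate, endpoint-wise on
#' frequency ranges. The exact ORF fraction is used, never the two-decimal
#' rendering: 6.0e-5 x (28/55) must give 3.05e-5, which does not reproduce
#' from the rounded rate 0.51. Not-determined cargo propagates to a
#' not-determined result.
#'
#' @param frequency a [transfer_frequency()].
#' @param cargo a [cargo_annotation()] or NA.
#' @return a \code{transfer_frequency}-shaped range on the mobility scale, or
#'   NA if cargo is not determined.
#' @examples
#' relative_mobility(transfer_frequency(2.46), cargo_annotation(4, 26))
#' @export
relative_mobility <- function(frequency, cargo) {
  if (!inherits(frequency, "transfer_frequency"))
    ltm_stop("frequency must be a transfer_frequency")
  rate <- cargo_capacity_rate(cargo)
  if (is.na(rate)) return(NA)
  transfer_frequency(frequency$lo * rate, frequency$hi * rate)
}

# dense rank, descending; ties share a rank
dense_rank_desc <- function(x) {
  lev <- sort(unique(x[!is.na(x)]), decreasing = TRUE)
  r <- match(x, lev)
  r[is.na(r)] <- length(lev) + 1L   # not-determined values rank last
  r
}

#' Assemble the comparative mobility ledger
#'
#' Builds one row per record with the normalised transfer frequency, the
#' cargo capacity rate, the relative frequency of genetic mobility, and dense
#' ranks by frequency and by mobility (descending on the upper endpoint; ties
#' share a rank; not-determined mobilities rank last). Rows are ordered by
#' descending frequency upper endpoint, then by \code{element_id}, so the
#' ledger is invariant to the input order.
#'
#' @param records a list of [mobility_record()] objects, or a records
#'   data.frame as returned by [read_mobility_records()].
#' @param calibrations named list of [donor_calibration()] objects keyed by
#'   organism tag; defaults to [builtin_calibrations()]. Required for records
#'   carrying a raw titre instead of a frequency.
#' @return a \code{data.frame} of class \code{mobility_ledger} with numeric
#'   columns at full precision plus rendered string columns
#'   (\code{cargo_rate_str}, \code{relative_mobility_str}).
#' @export
build_mobility_ledger <- function(records, calibrations = builtin_calibrations()) {
  if (is.data.frame(records)) records <- records_from_frame(records)
  if (!length(records))
    return(empty_ledger())
  ids <- vapply(records, `[[`, "", "element_id")
  if (anyDuplicated(ids))
    ltm_stop("duplicate element_id: %s", ids[duplicated(ids)][1])

  rows <- lapply(records, function(rec) {
    freq <- rec$frequency
    if (is.null(freq)) {
      cal <- calibrations[[rec$organism]]
      if (is.null(cal))
        ltm_stop("record '%s': no donor calibration for organism '%s'",
                 rec$element_id, rec$organism)
      freq <- transfer_frequency(
        normalize_transfer_frequency(rec$titre_tru_per_ml, cal))
    }
    rate <- cargo_capacity_rate(rec$cargo)
    rm <- relative_mobility(freq, rec$cargo)
    nd <- length(rm) == 1 && is.na(rm[1])
    data.frame(
      element_id = rec$element_id, accession = rec$accession,
      category = rec$category, mechanism = rec$mechanism,
      organism = rec$organism,
      freq_lo = freq$lo, freq_hi = freq$hi,
      accessory_orfs = if (inherits(rec$cargo, "cargo_annotation"))
        rec$cargo$accessory_orfs else NA_real_,
      total_orfs = if (inherits(rec$cargo, "cargo_annotation"))
        rec$cargo$total_orfs else NA_real_,
      cargo_rate = rate,
      relmob_lo = if (nd) NA_real_ else rm$lo,
      relmob_hi = if (nd) NA_real_ else rm$hi,
      cargo_rate_str = format_cargo_rate(rec$cargo),
      relative_mobility_str = if (nd) "ND" else format_frequency(rm),
      source = rec$source,
      stringsAsFactors = FALSE)
  })
  led <- do.call(rbind, rows)
  led$rank_by_frequency <- dense_rank_desc(led$freq_hi)
  led$rank_by_mobility <- dense_rank_desc(led$relmob_hi)
  led <- led[order(-led$freq_hi, led$element_id), , drop = FALSE]
  rownames(led) <- NULL
  class(led) <- c("mobility_ledger", "data.frame")
  led
}

empty_ledger <- function() {
  led <- data.frame(element_id = character(), accession = character(),
                    category = character(), mechanism = character(),
                    organism = character(),
                    freq_lo = numeric(), freq_hi = numeric(),
                    accessory_orfs = numeric(), total_orfs = numeric(),
                    cargo_rate = numeric(),
                    relmob_lo = numeric(), relmob_hi = numeric(),
                    cargo_rate_str = character(),
                    relative_mobility_str = character(),
                    source = character(),
                    rank_by_frequency = integer(),
                    rank_by_mobility = integer(), stringsAsFactors = FALSE)
  class(led) <- c("mobility_ledger", "data.frame")
  led
}

# convert a validated records data.frame into a list of mobility_record
records_from_frame <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    freq <- if (!is.na(r$freq_lo))
      transfer_frequency(r$freq_lo, if (is.na(r$freq_hi)) r$freq_lo else r$freq_hi)
    cargo <- if (!is.na(r$accessory_orfs) && !is.na(r$total_orfs))
      cargo_annotation(r$accessory_orfs, r$total_orfs) else NA
    mobility_record(
      element_id = r$element_id, category = r$category,
      mechanism = r$mechanism, frequency = freq, cargo = cargo,
      accession = if (is.na(r$accession)) "" else r$accession,
      organism = if (is.na(r$organism)) "" else r$organism,
      titre_tru_per_ml = r$titre_tru_per_ml,
      source = if (is.na(r$source)) "" else r$source)
  })
}
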