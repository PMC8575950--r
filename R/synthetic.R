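# Synthetic data: toy circular genomes with attB registries and labelled
# ORFs, markers at chosen headful distances, and element panels with known
# ground-truth mobilities. Everything is deterministic for a given seed.

#' Specification of a toy circular genome
#'
#' @param length genome length in bp (1-5 Mb emulates real bacterial
#'   chromosomes; smaller values are fine for geometry tests).
#' @param n_orfs number of ORFs to place.
#' @param accessory_fraction probability an ORF is accessory cargo.
#' @param attb_layout data.frame with columns \code{site_id}, \code{frac}
#'   (position as a fraction of the genome in [0, 1)) and \code{direction}
#'   (+1/-1).
#' @param markers optional data.frame with columns \code{marker_id},
#'   \code{site_id}, \code{hf} (target headful index >= 1) and \code{offset}
#'   (bp into the window; the marker is placed strictly inside window
#'   \code{hf} of that site so that [headful_index()] recovers \code{hf}
#'   exactly).
#' @param marker_length marker span in bp (default 1000).
#' @param seed integer seed.
#' @return an object of class \code{genome_spec}.
#' @export
genome_spec <- function(length = 2e6, n_orfs = 200, accessory_fraction = 0.2,
                        attb_layout = data.frame(site_id = "attB1", frac = 0.1,
                                                 direction = 1),
                        markers = NULL, marker_length = 1000, seed = 1L) {
  if (accessory_fraction < 0 || accessory_fraction > 1)
    ltm_stop("accessory_fraction must lie in [0, 1]")
  need <- c("site_id", "frac", "direction")
  if (!all(need %in% names(attb_layout)))
    ltm_stop("attb_layout needs columns %s", paste(need, collapse = ", "))
  if (any(attb_layout$frac < 0 | attb_layout$frac >= 1))
    ltm_stop("attb_layout fracs must lie in [0, 1)")
  if (!is.null(markers)) {
    mneed <- c("marker_id", "site_id", "hf", "offset")
    if (!all(mneed %in% names(markers)))
      ltm_stop("markers needs columns %s", paste(mneed, collapse = ", "))
    if (any(markers$hf < 1 | markers$hf != round(markers$hf)))
      ltm_stop("marker headful indices must be integers >= 1")
    if (!all(markers$site_id %in% attb_layout$site_id))
      ltm_stop("marker site_id not present in attb_layout")
  }
  structure(list(length = length, n_orfs = as.integer(n_orfs),
                 accessory_fraction = accessory_fraction,
                 attb_layout = attb_layout, markers = markers,
                 marker_length = marker_length, seed = as.integer(seed)),
            class = "genome_spec")
}

ltm_accessory_products <- c(
  "enterotoxin type A", "leukotoxin subunit E", "beta-lactam resistance protein",
  "cadmium resistance protein", "virulence factor EsxA",
  "fibronectin-binding adhesin", "tetracycline resistance protein")

ltm_core_products <- c(
  "DNA polymerase III subunit alpha", "ribosomal protein L2",
  "DNA gyrase subunit B", "elongation factor Tu",
  "cell division protein FtsZ", "isoleucine--tRNA ligase",
  "ATP synthase subunit beta", "chaperonin GroEL")

#' Generate a toy circular genome
#'
#' Builds an [annotated_genome()] matching the spec: random A/C/G/T sequence,
#' non-overlapping ORFs with ground-truth accessory/core labels (accessory
#' products are drawn from [default_accessory_keywords()]-matching strings),
#' attB sites at the requested fractional positions, and selectable markers
#' placed strictly inside the requested headful window of their site.
#' Optionally writes GenBank, GFF3+FASTA and an attB CSV. Deterministic for a
#' given seed (byte-identical files).
#'
#' @param spec a [genome_spec()].
#' @param model the [prophage_model()] defining the headful geometry for
#'   marker placement (default: built-in 80alpha model).
#' @param dir if non-NULL, directory into which \code{<genome_id>.gb},
#'   \code{<genome_id>.gff3}, \code{<genome_id>.fna} and
#'   \code{<genome_id>_attb.csv} are written.
#' @param genome_id identifier (default "toygenome").
#' @return the [annotated_genome()] (invisibly carries ground truth in the
#'   ORF \code{class} column and the marker loci).
#' @export
generate_toy_genome <- function(spec, model = builtin_prophage_models()$`80alpha`,
                                dir = NULL, genome_id = "toygenome") {
  stopifnot(inherits(spec, "genome_spec"), inherits(model, "prophage_model"))
  L <- spec$length
  H <- model$headful_size
  if (!is.null(spec$markers)) {
    if (any(spec$markers$hf > model$max_headfuls))
      ltm_stop("marker beyond LT reach: hf > max_headfuls (%d)",
               model$max_headfuls)
    if (any(spec$markers$offset < 0 |
            spec$markers$offset + spec$marker_length >= H))
      ltm_stop("marker offset must keep the marker strictly inside one window")
  }
  set.seed(spec$seed)
  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")

  # ORFs in equal slots so they never overlap; lengths are multiples of 3
  orfs <- empty_orfs()
  if (spec$n_orfs > 0) {
    slot <- L / spec$n_orfs
    max_len <- max(300, min(1500, 3 * floor((slot - 100) / 3)))
    if (max_len < 300) ltm_stop("genome too small for %d ORFs", spec$n_orfs)
    len <- 3 * sample(100:(max_len / 3), spec$n_orfs, replace = TRUE)
    offset <- floor(stats::runif(spec$n_orfs, 0, pmax(1, slot - len - 1)))
    start <- floor((seq_len(spec$n_orfs) - 1) * slot) + offset
    acc <- stats::runif(spec$n_orfs) < spec$accessory_fraction
    orfs <- data.frame(
      orf_id = sprintf("orf%04d", seq_len(spec$n_orfs)),
      start = start, length = len,
      strand = sample(c(1L, -1L), spec$n_orfs, replace = TRUE),
      product = ifelse(acc,
                       sample(ltm_accessory_products, spec$n_orfs, replace = TRUE),
                       sample(ltm_core_products, spec$n_orfs, replace = TRUE)),
      class = ifelse(acc, "accessory", "core"),
      stringsAsFactors = FALSE)
  }

  sites <- lapply(seq_len(nrow(spec$attb_layout)), function(i)
    attb_site(spec$attb_layout$site_id[i],
              floor(spec$attb_layout$frac[i] * L),
              spec$attb_layout$direction[i]))
  names(sites) <- spec$attb_layout$site_id

  loci <- list()
  if (!is.null(spec$markers)) {
    loci <- lapply(seq_len(nrow(spec$markers)), function(i) {
      mk <- spec$markers[i, ]
      s <- sites[[mk$site_id]]
      # place the packaging-proximal edge at (hf-1)*H + offset from the attB
      u <- (mk$hf - 1) * H + mk$offset
      start <- if (s$direction == 1) (s$position + u) %% L
               else (s$position - u - spec$marker_length) %% L
      genomic_locus(mk$marker_id,
                    circular_interval(start, spec$marker_length, L),
                    locus_class = "marker")
    })
  }

  genome <- annotated_genome(genome_id, L, circular = TRUE, orfs = orfs,
                             attb_sites = sites, loci = loci,
                             sequence = sequence)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genbank(genome, file.path(dir, paste0(genome_id, ".gb")))
    write_gff3_fasta(genome, file.path(dir, paste0(genome_id, ".gff3")),
                     file.path(dir, paste0(genome_id, ".fna")))
    write_attb_registry(sites, file.path(dir, paste0(genome_id, "_attb.csv")))
  }
  genome
}

#' Generate a synthetic element panel with known ground truth
#'
#' Draws \code{n_elements} mobility records with log-uniform transfer
#' frequencies over [1e-9, 1] (a minority as ranges), half-unit cargo
#' fractions, and a small fraction of not-determined cargo. The returned
#' frame carries ground-truth relative mobilities in \code{truth_relmob_lo} /
#' \code{truth_relmob_hi} columns (computed independently of the ledger
#' path), which [read_mobility_records()] preserves and
#' [build_mobility_ledger()] ignores.
#'
#' @param n_elements panel size.
#' @param seed integer seed.
#' @param nd_fraction fraction of records with not-determined cargo.
#' @param path optional CSV path to write the panel to.
#' @return data.frame of class \code{mobility_records} with truth columns.
#' @export
generate_element_panel <- function(n_elements, seed = 1L, nd_fraction = 0.1,
                                   path = NULL) {
  set.seed(seed)
  n <- n_elements
  cats <- sample(c("plasmid", "phage", "PICI", "conjugative_transposon"),
                 n, replace = TRUE)
  mech <- vapply(cats, function(cc) ltm_category_mechanisms[[cc]][1], "")
  lo <- 10^stats::runif(n, -9, 0)
  is_range <- stats::runif(n) < 0.3
  hi <- ifelse(is_range, pmin(1, lo * 10^stats::runif(n, 0.5, 2)), lo)
  total <- sample(10:200, n, replace = TRUE) / 2
  accessory <- vapply(total, function(t) sample(0:(2 * t), 1) / 2, 0)
  nd <- stats::runif(n) < nd_fraction
  accessory[nd] <- NA
  total[nd] <- NA
  df <- data.frame(
    element_id = sprintf("EL%03d", seq_len(n)),
    accession = "", category = cats, mechanism = mech, organism = "",
    freq_lo = lo, freq_hi = hi, titre_tru_per_ml = NA_real_,
    accessory_orfs = accessory, total_orfs = total,
    source = "synthetic",
    truth_relmob_lo = lo * accessory / total,
    truth_relmob_hi = hi * accessory / total,
    stringsAsFactors = FALSE)
  class(df) <- c("mobility_records", "data.frame")
  if (!is.null(path)) {
    con <- file(path, "wb")
    utils::write.csv(as.data.frame(df), con, row.names = FALSE, na = "")
    close(con)
  }
  df
}
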