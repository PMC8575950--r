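# Annotation I/O: GenBank and GFF3+FASTA genome annotations, accessory-ORF
# classification, ORF counting in headful windows, and the mobility-record
# table formats.

#' Annotated circular genome
#'
#' Container for a (toy or real) bacterial chromosome: length, topology, ORFs
#' with accessory/core class labels, attB site registry and loci of interest.
#' All coordinates are 0-based half-open with wrap-around modulo the genome
#' length.
#'
#' @param genome_id identifier.
#' @param length genome length in bp.
#' @param circular logical topology flag.
#' @param orfs data.frame with columns \code{orf_id}, \code{start},
#'   \code{length}, \code{strand} (+1/-1), \code{product},
#'   \code{class} (accessory/core/unassigned).
#' @param attb_sites optional list of [attb_site()]s.
#' @param loci optional list of [genomic_locus()]s.
#' @param sequence optional nucleotide sequence (character scalar).
#' @return an object of class \code{annotated_genome}.
#' @export
annotated_genome <- function(genome_id, length, circular = TRUE,
                             orfs = empty_orfs(), attb_sites = list(),
                             loci = list(), sequence = NULL) {
  stopifnot(is.numeric(length), length > 0)
  need <- c("orf_id", "start", "length", "strand", "product", "class")
  if (!all(need %in% names(orfs)))
    ltm_stop("orfs must have columns: %s", paste(need, collapse = ", "))
  if (nrow(orfs)) {
    if (anyDuplicated(orfs$orf_id))
      ltm_stop("duplicate orf_id: %s", orfs$orf_id[duplicated(orfs$orf_id)][1])
    if (any(orfs$start < 0 | orfs$start >= length))
      ltm_stop("ORF starts must lie in [0, L)")
    if (any(orfs$length <= 0 | orfs$length > length))
      ltm_stop("ORF lengths must satisfy 0 < length <= L")
    if (!all(orfs$class %in% c("accessory", "core", "unassigned")))
      ltm_stop("ORF class must be accessory, core or unassigned")
  }
  if (!is.null(sequence) && nchar(sequence) != length)
    ltm_stop("sequence length (%d) != declared genome length (%d)",
             nchar(sequence), length)
  structure(list(genome_id = as.character(genome_id), length = length,
                 circular = isTRUE(circular), orfs = orfs,
                 attb_sites = attb_sites, loci = loci, sequence = sequence),
            class = "annotated_genome")
}

empty_orfs <- function() {
  data.frame(orf_id = character(), start = numeric(), length = numeric(),
             strand = integer(), product = character(), class = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp (%s), %d ORFs, %d attB sites, %d loci\n",
              x$genome_id, as.integer(x$length),
              if (x$circular) "circular" else "linear",
              nrow(x$orfs), length(x$attb_sites), length(x$loci)))
  invisible(x)
}

#' Read a genome annotation
#'
#' Reads CDS features into ORFs. GenBank flat files carry their own length,
#' topology and sequence; GFF3 needs the companion FASTA for the sequence and
#' genome length. Features crossing the origin (GenBank \code{join} spanning
#' the end, or two GFF3 parts sharing an ID) become a single wrapped
#' interval. Coordinates are converted to 0-based half-open.
#'
#' @param path annotation file.
#' @param format \code{"genbank"} or \code{"gff3"}.
#' @param fasta FASTA path (required for GFF3).
#' @param circular topology override for GFF3 (GenBank reads it from LOCUS);
#'   default TRUE.
#' @return an [annotated_genome()].
#' @export
read_genome_annotation <- function(path, format = c("genbank", "gff3"),
                                   fasta = NULL, circular = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) ltm_stop("file not found: %s", path)
  if (format == "genbank") read_genbank(path)
  else read_gff3_fasta(path, fasta, circular = circular)
}

# ---- GenBank flat file (minimal dialect: LOCUS / FEATURES source+CDS / ORIGIN)

read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) ltm_stop("%s: no LOCUS line; not a GenBank flat file", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  genome_id <- toks[2]
  len <- suppressWarnings(as.numeric(toks[which(toks == "bp") - 1]))
  if (!length(len) || is.na(len))
    ltm_stop("%s: cannot determine sequence length from LOCUS line", path)
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  feat_at <- grep("^FEATURES", lines)
  orig_at <- grep("^ORIGIN", lines)
  end_at <- if (length(orig_at)) orig_at[1] else length(lines) + 1
  orfs <- empty_orfs()
  if (length(feat_at)) {
    block <- lines[(feat_at[1] + 1):(end_at - 1)]
    starts <- grep("^ {5}\\S", block)
    bounds <- c(starts, length(block) + 1L)
    recs <- lapply(seq_along(starts), function(i)
      block[bounds[i]:(bounds[i + 1] - 1L)])
    n <- 0
    for (rec in recs) {
      head <- strsplit(trimws(rec[1]), "\\s+")[[1]]
      if (head[1] != "CDS") next
      loc <- parse_gb_location(head[2], len)
      quals <- parse_gb_qualifiers(rec[-1])
      n <- n + 1
      orfs <- rbind(orfs, data.frame(
        orf_id = quals[["locus_tag"]] %||% sprintf("cds%04d", n),
        start = loc$start, length = loc$length, strand = loc$strand,
        product = quals[["product"]] %||% "",
        class = parse_class_note(quals[["note"]]),
        stringsAsFactors = FALSE))
    }
  }
  seq <- NULL
  if (length(orig_at)) {
    body <- lines[(orig_at[1] + 1):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(paste(gsub("[ 0-9]", "", body), collapse = ""))
    if (!nchar(seq)) seq <- NULL
  }
  annotated_genome(genome_id, len, circular, orfs, sequence = seq)
}

parse_gb_location <- function(loc, L) {
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    ab <- lapply(parts, function(p) as.numeric(strsplit(p, "\\.\\.")[[1]]))
    # origin-crossing feature: second segment resumes at base 1
    if (length(ab) != 2 || ab[[1]][2] != L || ab[[2]][1] != 1)
      ltm_stop("unsupported join location: %s", loc)
    list(start = ab[[1]][1] - 1, length = (L - ab[[1]][1] + 1) + ab[[2]][2],
         strand = strand)
  } else {
    ab <- as.numeric(strsplit(loc, "\\.\\.")[[1]])
    if (length(ab) != 2 || any(is.na(ab)))
      ltm_stop("unparseable location: %s", loc)
    list(start = ab[1] - 1, length = ab[2] - ab[1] + 1, strand = strand)
  }
}

parse_gb_qualifiers <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[grepl("^/", lines)]
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

parse_class_note <- function(note) {
  if (is.null(note)) return("unassigned")
  m <- regmatches(note, regexec("class:(\\w+)", note))[[1]]
  if (length(m) == 2 && m[2] %in% c("accessory", "core")) m[2] else "unassigned"
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits the standard minimal dialect: LOCUS (length + topology), FEATURES
#' with a source feature and one CDS per ORF (\code{complement()} for minus
#' strand, \code{join()} for origin-crossing features, \code{/locus_tag},
#' \code{/product} and a \code{/note="class:..."} carrying the
#' accessory/core label), and ORIGIN with the sequence.
#'
#' @param genome an [annotated_genome()] with a sequence.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (is.null(genome$sequence)) ltm_stop("genome carries no sequence")
  L <- as.integer(genome$length)
  con <- file(path, "wb")   # binary mode: LF endings, byte-stable output
  wr <- function(...) writeLines(sprintf(...), con, sep = "\n")
  wr("LOCUS       %s %d bp    DNA     %s BCT 01-JAN-2026",
     genome$genome_id, L, if (genome$circular) "circular" else "linear")
  wr("DEFINITION  synthetic toy genome.")
  wr("ACCESSION   %s", genome$genome_id)
  wr("FEATURES             Location/Qualifiers")
  wr("     source          1..%d", L)
  if (nrow(genome$orfs)) for (i in seq_len(nrow(genome$orfs))) {
    o <- genome$orfs[i, ]
    a <- o$start + 1
    b <- o$start + o$length
    loc <- if (b <= L) sprintf("%d..%d", a, b)
           else sprintf("join(%d..%d,1..%d)", a, L, b - L)
    if (o$strand == -1) loc <- sprintf("complement(%s)", loc)
    wr("     CDS             %s", loc)
    wr("                     /locus_tag=\"%s\"", o$orf_id)
    wr("                     /product=\"%s\"", o$product)
    wr("                     /note=\"class:%s\"", o$class)
  }
  wr("ORIGIN")
  seq <- tolower(genome$sequence)
  pos <- seq(1, nchar(seq), by = 60)
  for (p in pos) {
    chunk <- substring(seq, p, min(p + 59, nchar(seq)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    wr("%9d %s", p, paste(tens, collapse = " "))
  }
  wr("//")
  close(con)
  invisible(path)
}

# ---- GFF3 + FASTA (via rtracklayer / Biostrings)

read_gff3_fasta <- function(path, fasta, circular = TRUE) {
  if (is.null(fasta)) ltm_stop("GFF3 input needs the companion FASTA")
  dna <- Biostrings::readDNAStringSet(fasta)
  if (!length(dna)) ltm_stop("%s: empty FASTA", fasta)
  genome_id <- sub("\\s.*", "", names(dna)[1])
  L <- Biostrings::width(dna)[1]
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  df <- data.frame(id = as.character(gr$ID),
                   start = as.numeric(GenomicRanges::start(gr)) - 1,
                   end = as.numeric(GenomicRanges::end(gr)),
                   strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                                   -1L, 1L),
                   product = if (!is.null(gr$product)) as.character(gr$product)
                             else "",
                   class = if (!is.null(gr$locus_class))
                             as.character(gr$locus_class) else "unassigned",
                   stringsAsFactors = FALSE)
  orfs <- empty_orfs()
  for (id in unique(df$id)) {
    parts <- df[df$id == id, , drop = FALSE]
    if (nrow(parts) == 1) {
      start <- parts$start; len <- parts$end - parts$start
    } else if (nrow(parts) == 2) {
      # origin-crossing CDS split into [a, L) + [0, b)
      parts <- parts[order(-parts$start), ]
      if (parts$end[1] != L || parts$start[2] != 0)
        ltm_stop("CDS '%s': unsupported multi-part layout", id)
      start <- parts$start[1]
      len <- (L - parts$start[1]) + parts$end[2]
    } else ltm_stop("CDS '%s': more than two parts", id)
    orfs <- rbind(orfs, data.frame(
      orf_id = id, start = start, length = len, strand = parts$strand[1],
      product = parts$product[1],
      class = if (parts$class[1] %in% c("accessory", "core")) parts$class[1]
              else "unassigned",
      stringsAsFactors = FALSE))
  }
  annotated_genome(genome_id, L, circular, orfs,
                   sequence = as.character(dna[[1]]))
}

#' Write an annotated genome as GFF3 plus FASTA
#'
#' CDS features carry \code{ID}, \code{product} and \code{locus_class}
#' attributes; origin-crossing ORFs are split into two parts sharing an ID.
#'
#' @param genome an [annotated_genome()] with a sequence.
#' @param gff3_path,fasta_path output files.
#' @return \code{gff3_path}, invisibly.
#' @export
write_gff3_fasta <- function(genome, gff3_path, fasta_path) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (is.null(genome$sequence)) ltm_stop("genome carries no sequence")
  L <- as.integer(genome$length)
  rows <- list()
  if (nrow(genome$orfs)) for (i in seq_len(nrow(genome$orfs))) {
    o <- genome$orfs[i, ]
    for (p in linear_pieces(o$start, o$length, L))
      rows[[length(rows) + 1]] <- data.frame(
        start = p[1] + 1, end = p[2],
        strand = if (o$strand == -1) "-" else "+",
        ID = o$orf_id, product = o$product, locus_class = o$class,
        stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      seqnames = genome$genome_id,
      ranges = IRanges::IRanges(start = df$start, end = df$end),
      strand = df$strand, type = "CDS", ID = df$ID,
      phase = 0L, product = df$product, locus_class = df$locus_class)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  if (length(gr)) {
    GenomicRanges::seqinfo(gr) <- GenomeInfoDb_seqinfo(genome$genome_id, L,
                                                       genome$circular)
  }
  rtracklayer::export(gr, gff3_path, format = "gff3")
  dna <- Biostrings::DNAStringSet(stats::setNames(genome$sequence,
                                                  genome$genome_id))
  Biostrings::writeXStringSet(dna, fasta_path, width = 70)
  invisible(gff3_path)
}

GenomeInfoDb_seqinfo <- function(id, L, circular) {
  GenomeInfoDb::Seqinfo(seqnames = id, seqlengths = as.integer(L),
                        isCircular = circular)
}

# ---- attB registries

#' Read an attB site registry from CSV
#'
#' Expected columns: \code{site_id}, \code{position} (0-based bp),
#' \code{direction} (\code{+}/\code{-} or +1/-1), optional \code{phage_id}.
#'
#' @param path CSV file.
#' @return list of [attb_site()]s.
#' @export
read_attb_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "position", "direction")
  if (!all(need %in% names(df)))
    ltm_stop("%s: attB registry needs columns %s", path,
             paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    d <- df$direction[i]
    dir <- if (d %in% c("+", "+1", "1")) 1L
           else if (d %in% c("-", "-1")) -1L
           else ltm_stop("%s row %d: direction must be + or -", path, i)
    attb_site(df$site_id[i], df$position[i], dir,
              if ("phage_id" %in% names(df)) df$phage_id[i] else NA_character_)
  })
}

#' @rdname read_attb_registry
#' @param sites list of [attb_site()]s to write.
#' @export
write_attb_registry <- function(sites, path) {
  df <- data.frame(
    site_id = vapply(sites, `[[`, "", "site_id"),
    position = vapply(sites, `[[`, 0, "position"),
    direction = ifelse(vapply(sites, `[[`, 0L, "direction") == 1, "+", "-"),
    phage_id = vapply(sites, function(s) s$occupied %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- accessory classification

#' Accessory-ORF classification rules
#'
#' Manual accessory calls are made reproducible through explicit ORF id lists
#' plus case-insensitive product-text keywords. Precedence:
#' exclude > include > keywords.
#'
#' @param keyword_patterns character vector of regular expressions matched
#'   (case-insensitively) against ORF product text.
#' @param include_ids,exclude_ids explicit ORF id lists; must be disjoint.
#' @return an object of class \code{accessory_rules}.
#' @export
accessory_rules <- function(keyword_patterns = character(),
                            include_ids = character(),
                            exclude_ids = character()) {
  if (length(intersect(include_ids, exclude_ids)))
    ltm_stop("include_ids and exclude_ids must be disjoint")
  structure(list(keyword_patterns = keyword_patterns,
                 include_ids = include_ids, exclude_ids = exclude_ids),
            class = "accessory_rules")
}

#' Default accessory keywords
#'
#' Product-text patterns regarded as host-utilisable cargo (toxins,
#' resistance, virulence and colonisation factors) for synthetic data.
#' @return character vector of patterns.
#' @export
default_accessory_keywords <- function() {
  c("toxin", "enterotoxin", "leukotoxin", "resistance", "virulence",
    "adhesin", "lipoprotein")
}

#' Classify ORFs into accessory cargo
#'
#' @param genome an [annotated_genome()] (whole element or chromosome).
#' @param rules an [accessory_rules()].
#' @return a [cargo_annotation()] with accessory and total ORF counts.
#' @export
classify_orfs <- function(genome, rules = accessory_rules()) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(rules, "accessory_rules"))
  orfs <- genome$orfs
  total <- nrow(orfs)
  if (!total) ltm_stop("genome has no ORFs to classify")
  kw <- rep(FALSE, total)
  for (p in rules$keyword_patterns)
    kw <- kw | grepl(p, orfs$product, ignore.case = TRUE)
  acc <- (orfs$orf_id %in% rules$include_ids | kw) &
    !(orfs$orf_id %in% rules$exclude_ids)
  cargo_annotation(sum(acc), total)
}

#' Count ORFs in a headful window
#'
#' ORFs fully inside the window count 1; ORFs straddling a window edge count
#' \code{partial_weight} (0.5 by default, matching the half-ORF convention of
#' tabulated headful cargo counts such as 41.5/41.5).
#'
#' @param genome an [annotated_genome()].
#' @param window a [circular_interval()] on this genome.
#' @param partial_weight weight for straddling ORFs: 0, 0.5 or 1.
#' @return count (possibly half-integral).
#' @export
orfs_in_window <- function(genome, window, partial_weight = 0.5) {
  stopifnot(inherits(genome, "annotated_genome"),
            inherits(window, "circular_interval"))
  if (!partial_weight %in% c(0, 0.5, 1))
    ltm_stop("partial_weight must be 0, 0.5 or 1")
  if (window$L != genome$length)
    ltm_stop("window is not on this genome (L mismatch)")
  orfs <- genome$orfs
  if (!nrow(orfs)) return(0)
  ol <- vapply(seq_len(nrow(orfs)), function(i)
    circular_overlap(orfs$start[i], orfs$length[i],
                     window$start, window$length, genome$length), 0)
  full <- sum(ol == orfs$length & ol > 0)
  straddle <- sum(ol > 0 & ol < orfs$length)
  full + partial_weight * straddle
}

# ---- mobility record tables

ltm_record_columns <- c("element_id", "accession", "category", "mechanism",
                        "organism", "freq_lo", "freq_hi", "titre_tru_per_ml",
                        "accessory_orfs", "total_orfs", "source")

#' Read a mobility-record table from CSV
#'
#' Schema: columns \code{element_id}, \code{accession}, \code{category},
#' \code{mechanism}, \code{organism}, \code{freq_lo}, \code{freq_hi},
#' \code{titre_tru_per_ml}, \code{accessory_orfs}, \code{total_orfs},
#' \code{source}. Empty cells are not-determined. Each record must carry a
#' frequency (\code{freq_lo}, optionally \code{freq_hi}) or a titre. Extra
#' columns are preserved but ignored by the ledger. Violations are reported
#' with their row number.
#'
#' @param path CSV file.
#' @return data.frame of class \code{mobility_records}.
#' @export
read_mobility_records <- function(path) {
  if (!file.exists(path)) ltm_stop("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(ltm_record_columns, names(df))
  if (length(missing_cols))
    ltm_stop("%s: missing columns: %s", path,
             paste(missing_cols, collapse = ", "))
  for (cc in c("freq_lo", "freq_hi", "titre_tru_per_ml",
               "accessory_orfs", "total_orfs")) {
    v <- trimws(df[[cc]])
    v[v %in% c("", "ND")] <- NA
    df[[cc]] <- suppressWarnings(as.numeric(v))
  }
  validate_records(df, path)
  class(df) <- c("mobility_records", "data.frame")
  df
}

validate_records <- function(df, where = "records") {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    fail <- function(msg, ...)
      ltm_stop("%s row %d (%s): %s", where, i,
               if (nzchar(r$element_id)) r$element_id else "?",
               sprintf(msg, ...))
    if (!nzchar(r$element_id)) fail("element_id is empty")
    if (!r$category %in% names(ltm_category_mechanisms))
      fail("unknown category '%s'", r$category)
    if (!r$mechanism %in% ltm_category_mechanisms[[r$category]])
      fail("mechanism '%s' invalid for category '%s'", r$mechanism, r$category)
    if (is.na(r$freq_lo) && is.na(r$titre_tru_per_ml))
      fail("needs freq_lo or titre_tru_per_ml")
    if (!is.na(r$freq_lo) && r$freq_lo < 0) fail("negative frequency")
    if (xor(is.na(r$accessory_orfs), is.na(r$total_orfs)))
      fail("accessory_orfs and total_orfs must be given together")
    if (!is.na(r$accessory_orfs)) {
      if (r$total_orfs <= 0) fail("total_orfs must be > 0")
      if (r$accessory_orfs > r$total_orfs)
        fail("accessory_orfs exceeds total_orfs")
      if (any((c(r$accessory_orfs, r$total_orfs) * 2) %% 1 != 0))
        fail("ORF counts must have 0.5 granularity")
    }
  }
  if (anyDuplicated(df$element_id))
    ltm_stop("%s: duplicate element_id '%s'", where,
             df$element_id[duplicated(df$element_id)][1])
  invisible(df)
}

#' @rdname read_mobility_records
#' @param records a \code{mobility_records} data.frame to write.
#' @export
write_mobility_records <- function(records, path) {
  df <- as.data.frame(records)[, ltm_record_columns]
  con <- file(path, "wb")
  utils::write.csv(df, con, row.names = FALSE, na = "")
  close(con)
  invisible(path)
}

#' Write a mobility ledger as TSV (rendered) and JSON (full precision)
#'
#' The TSV mirrors the comparative-table layout: rendered frequency, cargo
#' rate with ORF counts, relative mobility and the two rank columns. The JSON
#' variant keeps all numeric columns at full double precision.
#'
#' @param ledger a ledger from [build_mobility_ledger()].
#' @param tsv_path output TSV path.
#' @param json_path output JSON path; default: TSV path with .json extension.
#' @return \code{tsv_path}, invisibly.
#' @export
write_ledger <- function(ledger, tsv_path,
                         json_path = sub("\\.tsv$", ".json", tsv_path)) {
  stopifnot(inherits(ledger, "mobility_ledger"))
  disp <- data.frame(
    element_id = ledger$element_id, accession = ledger$accession,
    category = ledger$category, mechanism = ledger$mechanism,
    transfer_frequency = vapply(seq_len(nrow(ledger)), function(i)
      format_frequency(transfer_frequency(ledger$freq_lo[i],
                                          ledger$freq_hi[i])), ""),
    cargo_capacity_rate = ledger$cargo_rate_str,
    relative_mobility = ledger$relative_mobility_str,
    rank_by_frequency = ledger$rank_by_frequency,
    rank_by_mobility = ledger$rank_by_mobility,
    source = ledger$source, stringsAsFactors = FALSE)
  utils::write.table(disp, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "ND")
  if (!is.null(json_path) && identical(json_path, tsv_path))
    json_path <- paste0(tsv_path, ".json")
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(ledger), json_path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tsv_path)
}
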