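# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's interval arithmetic: everything is done by explicit
# base-by-base walks or enumeration so they can disagree with buggy code.

# headful assignment for every base of the genome: walk base-by-base from the
# attB in the packaging direction, counting full headfuls. Returns an
# integer vector indexed by position + 1 (NA = out of reach).
oracle_per_base_hf <- function(site, model, L) {
  reach <- min(model$max_headfuls * model$headful_size, L)
  steps <- seq_len(reach) - 1
  pos <- if (site$direction == 1) (site$position + steps) %% L
         else (site$position - 1 - steps) %% L
  out <- rep(NA_integer_, L)
  out[pos + 1] <- as.integer(steps %/% model$headful_size) + 1L
  out
}

# union coverage by marking bases
oracle_coverage <- function(L, sites, model) {
  mark <- rep(FALSE, L)
  for (s in sites) mark <- mark | !is.na(oracle_per_base_hf(s, model, L))
  sum(mark)
}

# headful range of a locus from per-base marks (NA if out of reach)
oracle_locus_hf_range <- function(locus, site, model, L) {
  hf <- oracle_per_base_hf(site, model, L)
  pos <- (locus$span$start + seq_len(locus$span$length) - 1) %% L
  hit <- hf[pos + 1]
  hit <- hit[!is.na(hit)]
  if (!length(hit)) return(NA_character_)
  k <- range(hit)
  if (k[1] == k[2]) sprintf("HF %d", k[1]) else sprintf("HF %d-%d", k[1], k[2])
}

# two-pass mean / sample sd, coded independently of stats::sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  if (length(x) < 2) return(list(mean = m, sd = NA_real_))
  list(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# a small annotated genome built directly (not via the generator)
make_tiny_genome <- function(L = 50000, orf_table = NULL, sequence = NULL,
                             id = "tiny") {
  if (is.null(sequence)) {
    set.seed(99)
    sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = "")
  }
  if (is.null(orf_table)) orf_table <- ltmob:::empty_orfs()
  annotated_genome(id, L, circular = TRUE, orfs = orf_table,
                   sequence = sequence)
}

orf_row <- function(id, start, length, strand = 1L, product = "hypothetical",
                    class = "unassigned") {
  data.frame(orf_id = id, start = start, length = length, strand = strand,
             product = product, class = class, stringsAsFactors = FALSE)
}
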