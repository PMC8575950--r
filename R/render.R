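#' Render a value in table-style scientific notation
#'
#' Formats numbers the way comparative transfer-frequency tables print them:
#' a mantissa with a fixed number of significant figures times a power of ten
#' (e.g. \code{"3.78 × 10^-1"}), with exponent zero collapsed to the bare
#' mantissa (\code{"2.46"}).
#'
#' Rounding uses the C library's decimal formatting of the underlying double
#' (via \code{sprintf}) rather than \code{signif()}; the two differ on decimal
#' half-way cases such as 3.845e-4, which must round up to \code{3.85e-4} to
#' match tabulated values.
#'
#' @param x numeric vector.
#' @param sig number of significant figures (default 3).
#' @param style \code{"paper"} for \code{"a × 10^b"}, \code{"plain"} for
#'   C-style \code{"aEb"} notation.
#' @return character vector; \code{NA} maps to \code{"ND"}.
#' @examples
#' format_sci(2.46 * 4 / 26)       # "3.78 × 10^-1"
#' format_sci(1.57 * 5 / 70)       # "1.12 × 10^-1"
#' @export
format_sci <- function(x, sig = 3, style = c("paper", "plain")) {
  style <- match.arg(style)
  stopifnot(is.numeric(x), sig >= 1)
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) { out[i] <- "ND"; next }
    if (v == 0) { out[i] <- "0"; next }
    s <- sprintf("%.*e", sig - 1L, v)
    if (style == "plain") { out[i] <- s; next }
    parts <- strsplit(s, "e", fixed = TRUE)[[1]]
    expo <- as.integer(parts[2])
    out[i] <- if (expo == 0L) parts[1] else {
      paste0(parts[1], " × 10^", expo)
    }
  }
  out
}

#' Parse table-style scientific notation back to numeric
#'
#' Inverse of [format_sci()]: accepts \code{"3.78 × 10^-1"},
#' \code{"3.78 x 10^-1"}, plain numbers, and \code{"ND"} (returned as NA).
#' Unicode minus signs are normalised.
#'
#' @param s character vector.
#' @return numeric vector.
#' @export
parse_sci <- function(s) {
  s <- gsub("−", "-", s)
  s <- gsub("\\s*[×x]\\s*10\\^", "e", s)
  ifelse(trimws(s) %in% c("", "ND", "—"), NA_real_, as.numeric(s))
}

#' Render a cargo capacity rate with its ORF counts
#'
#' Produces the two-decimal rendering used in mobility tables, optionally with
#' the exact accessory/total ORF counts in brackets, e.g. \code{"0.15 (4/26)"}.
#' Half-unit ORF counts print as-is (\code{"41.5/41.5"}).
#'
#' @param cargo a [cargo_annotation()] object, or NA for not-determined.
#' @param counts include the bracketed counts? (default TRUE)
#' @return a character scalar; \code{"ND"} for missing cargo.
#' @export
format_cargo_rate <- function(cargo, counts = TRUE) {
  if (is.null(cargo) || (length(cargo) == 1 && is.na(cargo[1]))) return("ND")
  stopifnot(inherits(cargo, "cargo_annotation"))
  rate <- sprintf("%.2f", cargo$accessory_orfs / cargo$total_orfs)
  if (!counts) return(rate)
  sprintf("%s (%s/%s)", rate, fmt_orf_count(cargo$accessory_orfs),
          fmt_orf_count(cargo$total_orfs))
}

# drop the ".0" from whole half-unit counts: 39 -> "39", 41.5 -> "41.5"
fmt_orf_count <- function(x) {
  ifelse(x == floor(x), sprintf("%d", as.integer(x)), sprintf("%.1f", x))
}

#' Render a transfer-frequency (or relative-mobility) range
#'
#' Point values render as a single number; true ranges render as
#' \code{"<first> to <second>"}. Tables print some ranges high-to-low; the
#' order is configurable.
#'
#' @param freq a [transfer_frequency()] object or NA.
#' @param sig significant figures (default 3).
#' @param order \code{"desc"} (high to low, the common table style) or
#'   \code{"asc"}.
#' @param style passed to [format_sci()].
#' @return character scalar.
#' @export
format_frequency <- function(freq, sig = 3, order = c("desc", "asc"),
                             style = "paper") {
  order <- match.arg(order)
  if (is.null(freq) || (length(freq) == 1 && is.na(freq[1]))) return("ND")
  stopifnot(inherits(freq, "transfer_frequency"))
  if (!freq$is_range) return(format_sci(freq$lo, sig, style))
  ends <- if (order == "desc") c(freq$hi, freq$lo) else c(freq$lo, freq$hi)
  paste(format_sci(ends, sig, style), collapse = " to ")
}
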