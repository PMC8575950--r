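# Packaged fixture: curated published transfer datasets for S. aureus and
# Salmonella, the donor calibrations, and the prophage packaging models.
#
# The record tables store the raw inputs (transfer frequencies or ranges as
# reported, accessory/total ORF counts) together with the published derived
# cells (printed_cargo_rate, printed_relmob_lo / printed_relmob_hi, paired to
# freq_lo / freq_hi respectively) and a `discrepancy` column flagging cells
# whose published value does not reproduce from the raw inputs. Flagged
# cells: the Tn916 relative-mobility endpoint derived from its upper
# conjugation frequency, the SaPI2 cargo-rate and relative-mobility cells,
# and the P22 lysogenisation TE/donor rendering in the replicate table.
# Flagged values are transcribed as printed, never silently corrected.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ltmob")
  if (!nzchar(p)) ltm_stop("packaged fixture '%s' not found", file)
  p
}

#' Packaged comparative-mobility fixture
#'
#' The curated transfer datasets underlying the comparative mobility
#' analysis: one record table per organism (*S. aureus*: plasmids, phages,
#' SaPIs, conjugative transposons and cadmium-resistance chromosomal markers
#' at defined headful distances; *Salmonella*: plasmids, phage P22, ICEs and
#' tetracycline-resistance markers), the replicate transduction assays with
#' raw mean titres, the OD-to-CFU donor calibrations, and the prophage
#' packaging models.
#'
#' @return a list with elements \code{saureus_records} and
#'   \code{salmonella_records} (validated \code{mobility_records} frames with
#'   published derived cells and discrepancy flags as extra columns),
#'   \code{replicate_assays} (data.frame of mean titres),
#'   \code{calibrations} (named list of [donor_calibration()]) and
#'   \code{models} (named list of [prophage_model()]).
#' @examples
#' fx <- mobility_fixture()
#' ledger <- build_mobility_ledger(fx$saureus_records, fx$calibrations)
#' ledger[ledger$element_id == "SaPI1", "relative_mobility_str"]
#' @export
mobility_fixture <- function() {
  cal_df <- utils::read.csv(fixture_path("calibrations.csv"),
                            stringsAsFactors = FALSE)
  calibrations <- stats::setNames(
    lapply(seq_len(nrow(cal_df)), function(i)
      donor_calibration(cal_df$organism[i], cal_df$od_landmark[i],
                        cal_df$donor_cfu_per_ml[i])),
    cal_df$organism)
  mod_df <- utils::read.csv(fixture_path("prophage_models.csv"),
                            stringsAsFactors = FALSE)
  models <- stats::setNames(
    lapply(seq_len(nrow(mod_df)), function(i)
      prophage_model(mod_df$phage_id[i], mod_df$headful_size[i],
                     mod_df$max_headfuls[i],
                     hf1_phage_carryover = mod_df$hf1_phage_carryover[i])),
    mod_df$phage_id)
  list(
    saureus_records = read_mobility_records(
      fixture_path("table_saureus_records.csv")),
    salmonella_records = read_mobility_records(
      fixture_path("table_salmonella_records.csv")),
    replicate_assays = utils::read.csv(
      fixture_path("table_replicate_assays.csv"), stringsAsFactors = FALSE),
    calibrations = calibrations,
    models = models)
}

#' Build the two fixture ledgers
#'
#' Convenience wrapper: [build_mobility_ledger()] applied to each packaged
#' record table with the packaged calibrations.
#'
#' @return named list of \code{mobility_ledger}s (\code{s_aureus},
#'   \code{salmonella}).
#' @export
fixture_ledgers <- function() {
  fx <- mobility_fixture()
  list(s_aureus = build_mobility_ledger(fx$saureus_records, fx$calibrations),
       salmonella = build_mobility_ledger(fx$salmonella_records,
                                          fx$calibrations))
}
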