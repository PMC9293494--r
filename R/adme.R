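#' ADME activity thresholds
#'
#' The classical TCMSP-style activity screen keeps compounds with oral
#' bioavailability OB >= 30 percent and drug-likeness DL >= 0.18; both
#' cut-offs are inclusive by default because several well-known active
#' herbal ingredients (e.g. quinizarin at DL 0.19, aurantio-obtusin at
#' OB 31.55) sit close to the boundary.
#'
#' @param ob_min Minimum oral bioavailability, percent. Default 30.
#' @param dl_min Minimum drug-likeness, dimensionless. Default 0.18.
#' @param inclusive If `TRUE` (default) the comparisons are `>=`,
#'   otherwise strict `>`.
#' @return A list of class `adme_thresholds`.
#' @export
adme_thresholds <- function(ob_min = 30, dl_min = 0.18, inclusive = TRUE) {
  stopifnot(is.numeric(ob_min), length(ob_min) == 1, ob_min >= 0,
            is.numeric(dl_min), length(dl_min) == 1,
            dl_min >= 0, dl_min <= 1,
            is.logical(inclusive), length(inclusive) == 1)
  structure(list(ob_min = ob_min, dl_min = dl_min, inclusive = inclusive),
            class = "adme_thresholds")
}

#' Filter active compounds by OB and DL
#'
#' Applies the ADME activity screen to a compound table. A compound is
#' active when its OB and DL both meet their thresholds; failing compounds
#' are annotated with which criterion failed. Input order is preserved.
#'
#' @param records Compound data.frame from [read_compound_table()] (or any
#'   data.frame with `mol_id`, `ob`, `dl`).
#' @param thresholds An [adme_thresholds()] object.
#' @return A list with `active` (the active subset, `is_active = TRUE`),
#'   `report` (all records plus logical `pass_ob`, `pass_dl`, `is_active`
#'   and a `failed` factor in
#'   `c("none", "ob", "dl", "both")`).
#' @examples
#' tab <- read_compound_table(system.file("extdata",
#'   "cassiae_semen_compounds.tsv", package = "herbnetpharm"))
#' res <- filter_active_compounds(tab)
#' nrow(res$active)  # 13: every Cassiae semen compound passes
#' @export
filter_active_compounds <- function(records, thresholds = adme_thresholds()) {
  stopifnot(inherits(thresholds, "adme_thresholds"))
  validate_compounds(records)
  cmp <- if (thresholds$inclusive) `>=` else `>`
  pass_ob <- cmp(records$ob, thresholds$ob_min)
  pass_dl <- cmp(records$dl, thresholds$dl_min)
  report <- records
  report$pass_ob <- pass_ob
  report$pass_dl <- pass_dl
  report$is_active <- pass_ob & pass_dl
  report$failed <- factor(
    ifelse(report$is_active, "none",
           ifelse(!pass_ob & !pass_dl, "both",
                  ifelse(!pass_ob, "ob", "dl"))),
    levels = c("none", "ob", "dl", "both")
  )
  active <- report[report$is_active,
                   intersect(c("mol_id", "name", "ob", "dl", "is_active"),
                             names(report)),
                   drop = FALSE]
  rownames(active) <- NULL
  list(active = active, report = report)
}

#' Summarise an ADME screen
#'
#' @param report The `report` data.frame from [filter_active_compounds()].
#' @return One-row data.frame with `n_total`, `n_active`, `n_failed_ob`,
#'   `n_failed_dl`, `n_failed_both`; the four outcome counts always sum to
#'   `n_total`.
#' @export
screen_summary <- function(report) {
  stopifnot(is.data.frame(report), "failed" %in% names(report))
  tab <- table(report$failed)
  data.frame(
    n_total = nrow(report),
    n_active = as.integer(tab[["none"]]),
    n_failed_ob = as.integer(tab[["ob"]]),
    n_failed_dl = as.integer(tab[["dl"]]),
    n_failed_both = as.integer(tab[["both"]])
  )
}
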