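# Human-readable and machine-readable decomposition reports.

fmt_kcal <- function(x) sprintf("%.2f", round(x * HARTREE_TO_KCAL, 2) + 0)

#' Write decomposition reports
#'
#' Emits a text table in kcal/mol (two decimals, interaction-term row order:
#' interaction, orbital, Pauli, electrostatic, dispersion, MP2 correlation,
#' corrections) plus the channel table and closure residual, and a
#' machine-readable JSON document carrying full-precision Hartree values.
#'
#' @param eda an `nocv_eda`.
#' @param nocv optional `nocv_result`.
#' @param path_txt,path_json output paths (`NULL` to skip one of them).
#' @return named list of written paths, invisibly.
#' @export
write_report <- function(eda, nocv = NULL, path_txt = NULL, path_json = NULL) {
  t <- eda$terms
  rows <- c(
    sprintf("dE_int    %10s", fmt_kcal(t$dE_int)),
    sprintf("dE_orb    %10s", fmt_kcal(t$dE_orb)),
    sprintf("dE_Pauli  %10s", fmt_kcal(t$dE_pauli)),
    sprintf("dE_elstat %10s", fmt_kcal(t$dE_elstat)),
    sprintf("dE_disp   %10s", fmt_kcal(t$dE_disp)))
  if (eda$method$mp2_coefficient > 0)
    rows <- c(rows, sprintf("dE_C_MP2  %10s", fmt_kcal(t$dE_mp2)))
  if (t$dE_corrections != 0)
    rows <- c(rows, sprintf("dE_corr   %10s", fmt_kcal(t$dE_corrections)))
  if (t$prep_available)
    rows <- c(rows, sprintf("dE_prep   %10s", fmt_kcal(t$dE_prep)),
              sprintf("dE_bind   %10s", fmt_kcal(t$dE_binding)))
  lines <- c("ETS decomposition (kcal/mol)", rows, "")
  if (!is.null(nocv)) {
    lines <- c(lines, "NOCV channels",
               sprintf("%3s %-10s %10s %12s", "k", "spin", "v_k", "dE_orb,k"),
               vapply(nocv$channels, function(ch)
                 sprintf("%3d %-10s %10.5f %12.2f", ch$k, ch$spin, ch$v,
                         ch$dE * HARTREE_TO_KCAL), ""),
               "")
  }
  lines <- c(lines, sprintf("closure residual %.3e Ha", t$closure_residual))
  out <- list()
  if (!is.null(path_txt)) {
    writeLines(lines, path_txt)
    out$txt <- path_txt
  }
  if (!is.null(path_json)) {
    doc <- list(units = "Hartree",
                terms = t[!vapply(t, is.logical, logical(1))],
                prep_available = t$prep_available,
                method = list(method = eda$method$method,
                              basis = eda$method$basis,
                              mp2_coefficient = eda$method$mp2_coefficient,
                              dispersion = eda$method$dispersion))
    if (!is.null(nocv)) {
      doc$channels <- lapply(nocv$channels, function(ch)
        list(k = ch$k, spin = ch$spin, v = ch$v, dE = ch$dE))
      doc$valence <- nocv$valence
      doc$channel_sum = nocv$channel_sum
    }
    jsonlite::write_json(doc, path_json, auto_unbox = TRUE, digits = NA)
    out$json <- path_json
  }
  invisible(out)
}
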