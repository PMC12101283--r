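#' Call ELISA hits at an absorbance-ratio threshold
#'
#' Single-clone ELISA screening after the final biopanning round: each clone
#' is read against a target-coated well and a BSA control well, and clones
#' whose A450 ratio (target / control) strictly exceeds the threshold are
#' called as candidate binders. The reference workflow uses a threshold of
#' 1.9. Rows whose control absorbance falls below `control_floor` would
#' produce unbounded ratios and are excluded and flagged instead.
#'
#' @param table Data frame with columns `clone_id`, `a450_target`,
#'   `a450_control` (absorbances >= 0).
#' @param ratio_threshold Ratio that must be strictly exceeded (default 1.9).
#' @param control_floor Minimum usable control absorbance (default 0.01).
#' @return Object of class `elisa_hits`: `hits` (tibble ordered by
#'   descending ratio), `n_hits`, `flagged` (excluded rows), `table`
#'   (all usable rows with ratios), `ratio_threshold`.
#' @examples
#' plate <- make_elisa_plate(n_rows = 12, n_true_hits = 3, seed = 1)
#' call_hits(plate)
#' @export
call_hits <- function(table, ratio_threshold = 1.9, control_floor = 0.01) {
  if (ratio_threshold <= 0) abort("ratio_threshold must be > 0")
  need <- c("clone_id", "a450_target", "a450_control")
  if (!all(need %in% names(table))) {
    abort(paste0("ELISA table needs columns: ", paste(need, collapse = ", ")))
  }
  tab <- tibble::as_tibble(table)
  if (any(tab$a450_target < 0, na.rm = TRUE) ||
      any(tab$a450_control < 0, na.rm = TRUE)) {
    abort("absorbances must be >= 0")
  }
  usable <- !is.na(tab$a450_control) & tab$a450_control >= control_floor
  flagged <- tab[!usable, ]
  tab <- tab[usable, ]
  tab$ratio <- tab$a450_target / tab$a450_control
  hits <- tab[tab$ratio > ratio_threshold, ]
  hits <- hits[order(-hits$ratio, hits$clone_id), ]
  structure(
    list(hits = hits, n_hits = nrow(hits), flagged = flagged,
         table = tab, ratio_threshold = ratio_threshold),
    class = "elisa_hits")
}

#' @export
print.elisa_hits <- function(x, ...) {
  cat(sprintf("<elisa_hits> %d of %d clones exceed ratio %.2f (%d flagged)\n",
              x$n_hits, nrow(x$table) + nrow(x$flagged), x$ratio_threshold,
              nrow(x$flagged)))
  if (x$n_hits > 0) print(head(x$hits, 10))
  invisible(x)
}
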