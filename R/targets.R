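#' Infer myocardial scar from segmental features
#'
#' A segment is flagged as scar if any of the rules fires: a visible scar
#' label (e.g. a late-enhancement read supplied upstream), wall thinning
#' below the thickness threshold, hypoattenuation below the attenuation
#' threshold (only when attenuation values are supplied), or akinesis
#' (peak |area change| below the akinesis threshold).
#'
#' @param features data.frame with columns `segment`, `visible_scar`
#'   (logical), `wall_thickness` (mm), `peak_area_change` (signed peak of
#'   the area-change curve; its magnitude is used), and optionally
#'   `attenuation`.
#' @param thinning_mm wall-thinning threshold, mm (default 6).
#' @param akinesis minimum peak |area change| (default 0.05).
#' @param hypoattenuation attenuation threshold; `NULL` (default)
#'   disables the rule.
#' @param require_thickness error on missing thickness values (default
#'   `TRUE`); set `FALSE` to disable the thinning rule where thickness is
#'   `NA`.
#' @return data.frame: `segment`, one logical column per rule
#'   (`scar_visible`, `scar_thinning`, `scar_hypoattenuation`,
#'   `akinetic`), and `scar` (any rule).
#' @export
infer_scar <- function(features, thinning_mm = 6, akinesis = 0.05,
                       hypoattenuation = NULL, require_thickness = TRUE) {
  need <- c("segment", "visible_scar", "wall_thickness", "peak_area_change")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  th <- features$wall_thickness
  if (any(is.na(th))) {
    if (require_thickness) stop("missing wall thickness values")
  }
  out <- data.frame(segment = features$segment)
  out$scar_visible <- isTRUE_v(features$visible_scar)
  out$scar_thinning <- !is.na(th) & th < thinning_mm
  out$scar_hypoattenuation <- if (!is.null(hypoattenuation) &&
                                  "attenuation" %in% names(features))
    !is.na(features$attenuation) & features$attenuation < hypoattenuation
  else rep(FALSE, nrow(features))
  out$akinetic <- !is.na(features$peak_area_change) &
    abs(features$peak_area_change) < akinesis
  out$scar <- out$scar_visible | out$scar_thinning |
    out$scar_hypoattenuation | out$akinetic
  out
}

isTRUE_v <- function(x) !is.na(x) & as.logical(x)

#' Select CRT target segments
#'
#' Applies the eligibility rules on the 16-segment model: septal segments
#' (2, 3, 8, 9, 14) are always excluded, as are scar-flagged and
#' low-amplitude (minimal endocardial strain) segments. The remaining
#' segments are ranked by descending time-to-peak contraction; ties are
#' broken by larger peak contraction magnitude, then by lower segment
#' number. The full ranking is retained so a "next adjacent vein" fallback
#' has ordered alternatives.
#'
#' @param ttp a `ttp_map` from [time_to_peak()] covering segments 1..16.
#' @param scar data.frame from [infer_scar()] (or any frame with `segment`
#'   and logical scar rule columns); `NULL` means no scar information.
#' @param n_targets how many top-ranked segments to report as targets.
#' @return Object of class `target_report`: list with `table` (per-segment
#'   eligibility, reasons, rank), `ranking` (eligible ids, best first),
#'   `targets` (top id(s); empty if none) and `reason` (when empty).
#' @export
select_targets <- function(ttp, scar = NULL, n_targets = 1L) {
  if (!all(1:16 %in% ttp$segment))
    stop("ttp must cover all 16 segments")
  tab <- ttp[ttp$segment %in% 1:16, c("segment", "ttp", "peak",
                                      "low_amplitude")]
  tab <- tab[order(tab$segment), ]
  reasons <- vector("list", 16L)
  for (s in aha_septal_segments()) reasons[[s]] <- "septal"
  if (!is.null(scar)) {
    for (i in seq_len(nrow(scar))) {
      s <- scar$segment[i]
      if (s < 1 || s > 16) next
      for (rule in c("scar_visible", "scar_thinning",
                     "scar_hypoattenuation", "akinetic"))
        if (rule %in% names(scar) && isTRUE_v(scar[[rule]][i]))
          reasons[[s]] <- c(reasons[[s]], rule)
    }
  }
  low <- which(isTRUE_v(tab$low_amplitude))
  for (s in low) reasons[[s]] <- c(reasons[[s]], "low_strain")
  eligible <- vapply(reasons, is.null, logical(1))
  tab$eligible <- eligible
  tab$reasons <- vapply(reasons, function(r)
    paste(unique(r), collapse = ";"), character(1))
  ord <- order(-tab$ttp, -abs(tab$peak), tab$segment)
  ranking <- tab$segment[ord][tab$eligible[ord]]
  tab$rank <- NA_integer_
  tab$rank[match(ranking, tab$segment)] <- seq_along(ranking)
  if (!length(ranking)) {
    rep <- list(table = tab, ranking = integer(), targets = integer(),
                reason = "no_eligible_segments")
  } else {
    rep <- list(table = tab, ranking = ranking,
                targets = utils::head(ranking, n_targets), reason = NULL)
  }
  structure(rep, class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  if (length(x$targets)) {
    cat("target segment(s):",
        paste(sprintf("%d (%s)", x$targets,
                      aha_segment_names()[x$targets]), collapse = ", "), "\n")
    cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  } else {
    cat("no eligible target segment:", x$reason, "\n")
  }
  excl <- x$table[!x$table$eligible, ]
  if (nrow(excl))
    cat("excluded:",
        paste(sprintf("%d[%s]", excl$segment, excl$reasons),
              collapse = " "), "\n")
  invisible(x)
}
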