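#' Colony counts for one 96-well plate
#'
#' Holds the 8 x 12 grid of colony counts (colonies of at least 50
#' cells) together with the seeding density and the per-column
#' irradiation condition (dose in Gy and dose-averaged LET in keV/um).
#' All 8 wells of a column share one condition.
#'
#' @param counts 8 x 12 integer matrix of non-negative colony counts;
#'   rows are plate rows A-H, columns plate columns 1-12.
#' @param seeded_per_well Cells seeded per well (> 0, default 100).
#' @param conditions Data frame with columns `column`, `dose_Gy`,
#'   `let_keV_um` mapping each plate column to its condition.
#' @param plate_id,replicate_id Identifiers.
#' @return An object of class `plate_counts`.
#' @export
plate_counts <- function(counts, seeded_per_well = 100, conditions = NULL,
                         plate_id = "plate1", replicate_id = 1L) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(8L, 12L))) stop("counts must be an 8 x 12 grid")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("colony counts must be non-negative")
  }
  if (seeded_per_well <= 0) stop("seeded_per_well must be > 0")
  if (!is.null(conditions)) {
    need <- c("column", "dose_Gy", "let_keV_um")
    if (!all(need %in% names(conditions))) {
      stop("conditions must have columns 'column', 'dose_Gy', 'let_keV_um'")
    }
  }
  dimnames(counts) <- list(LETTERS[1:8], 1:12)
  structure(list(counts = counts, seeded_per_well = seeded_per_well,
                 conditions = conditions, plate_id = plate_id,
                 replicate_id = replicate_id),
            class = "plate_counts")
}

#' @export
print.plate_counts <- function(x, ...) {
  cat(sprintf("<plate_counts> %s (replicate %s), %d cells seeded per well\n",
              x$plate_id, x$replicate_id, x$seeded_per_well))
  print(x$counts)
  invisible(x)
}

#' Plating efficiency from unirradiated control wells
#'
#' PE = mean(control colony counts) / cells seeded, with the standard
#' error of the mean taken across wells.
#'
#' @param control_counts Colony counts of unirradiated wells.
#' @param seeded_per_well Cells seeded per well.
#' @return A list with `pe`, `sem` and `n_wells`.
#' @export
plating_efficiency <- function(control_counts, seeded_per_well = 100) {
  if (length(control_counts) == 0L) stop("at least one control well is required")
  if (seeded_per_well <= 0) stop("seeded_per_well must be > 0")
  n <- length(control_counts)
  pe <- mean(control_counts) / seeded_per_well
  sem <- if (n > 1) stats::sd(control_counts) / sqrt(n) / seeded_per_well else 0
  list(pe = pe, sem = sem, n_wells = n)
}

#' Pool plates into per-condition survival fractions
#'
#' For each irradiation condition (plate column), pools the replicate
#' wells across plates and normalises the mean colony count by the
#' plating efficiency: SF = mean(counts) / (seeded * PE), with the
#' standard error of the mean across wells on the same scale. With two
#' plates per dose level, each condition rests on 16 replicate wells.
#'
#' @param plates A [plate_counts()] object or a list of them sharing a
#'   condition map and seeding density.
#' @param pe Plating efficiency (fraction in (0, 1]).
#' @return A data frame of class `survival_points` with one row per
#'   condition: `column`, `dose_Gy`, `let_keV_um`, `sf`, `sem`,
#'   `n_wells`, `cells_eff` (seeded * PE, the denominator used).
#' @export
survival_fractions <- function(plates, pe) {
  if (inherits(plates, "plate_counts")) plates <- list(plates)
  stopifnot(length(plates) >= 1L, all(vapply(plates, inherits, logical(1), "plate_counts")))
  if (pe <= 0) stop("plating efficiency must be > 0")
  seeded <- plates[[1]]$seeded_per_well
  cond <- plates[[1]]$conditions
  if (is.null(cond)) stop("plates must carry a condition map")
  rows <- lapply(seq_len(nrow(cond)), function(i) {
    col <- cond$column[i]
    wells <- unlist(lapply(plates, function(p) p$counts[, col]))
    wells <- wells[is.finite(wells)]
    if (length(wells) == 0L) {
      warning(sprintf("condition for column %d has no wells; skipped", col))
      return(NULL)
    }
    denom <- seeded * pe
    data.frame(column = col, dose_Gy = cond$dose_Gy[i],
               let_keV_um = cond$let_keV_um[i],
               sf = mean(wells) / denom,
               sem = if (length(wells) > 1)
                 stats::sd(wells) / sqrt(length(wells)) / denom else 0,
               n_wells = length(wells), cells_eff = denom)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("survival_points", "data.frame")
  out
}

#' Limit of detection of the clonogenic screen
#'
#' One colony per well sets the smallest measurable surviving
#' fraction: LOD = 1 / (cells plated * plating efficiency).
#'
#' @param seeded_per_well Cells seeded per well.
#' @param pe Plating efficiency.
#' @return The LOD threshold (unitless SF).
#' @export
lod_threshold <- function(seeded_per_well, pe) {
  if (seeded_per_well <= 0 || pe <= 0) stop("seeded_per_well and pe must be > 0")
  1 / (seeded_per_well * pe)
}

#' Drop survival points below the limit of detection
#'
#' Removes points whose aggregate SF is strictly below
#' 1/(cells plated * PE); points exactly at the threshold are
#' retained. Order is preserved.
#'
#' @param points A survival-point data frame (see
#'   [survival_fractions()]).
#' @param seeded_per_well Cells seeded per well.
#' @param pe Plating efficiency.
#' @return The filtered data frame.
#' @export
lod_filter <- function(points, seeded_per_well = 100, pe = 1) {
  thr <- lod_threshold(seeded_per_well, pe)
  points[points$sf >= thr, , drop = FALSE]
}
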