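#' Track-step event stream
#'
#' A stream of (energy deposition, step length) pairs scored in the
#' cell layer. The ratio epsilon/l of each step is the event-level LET;
#' energy deposition acts as the dose weight when averaging.
#'
#' @param epsilon_keV Energy deposition per step, keV (>= 0).
#' @param length_um Step length, micrometres (> 0).
#' @return A data frame of class `track_steps`.
#' @export
track_steps <- function(epsilon_keV, length_um) {
  if (length(epsilon_keV) != length(length_um)) {
    stop("epsilon and step length must have the same length")
  }
  if (any(!is.finite(epsilon_keV)) || any(epsilon_keV < 0)) {
    stop("energy depositions must be >= 0")
  }
  if (any(!is.finite(length_um)) || any(length_um <= 0)) {
    stop("step lengths must be > 0")
  }
  structure(data.frame(epsilon_keV = epsilon_keV, length_um = length_um),
            class = c("track_steps", "data.frame"))
}

#' Track- and dose-averaged LET of an event stream
#'
#' Treating epsilon/l as a random variable form of LET:
#' the track average is LET_t = sum(epsilon) / sum(l), and the dose
#' average weights each step's epsilon/l by its energy deposition,
#' LET_d = sum(epsilon * epsilon/l) / sum(epsilon). By the
#' Cauchy-Schwarz inequality LET_d >= LET_t, with equality exactly when
#' epsilon/l is constant across steps. The dose-weighted epsilon/l
#' spectrum is also returned as a histogram. Zero-epsilon steps
#' contribute path length to LET_t but carry no dose weight.
#'
#' @param events A [track_steps()] data frame (or any data frame with
#'   columns `epsilon_keV`, `length_um`).
#' @param bins Number of log-spaced histogram bins over the observed
#'   epsilon/l range of dose-carrying steps.
#' @return An object of class `let_result`: a list with `let_track`,
#'   `let_dose` (keV/um), `n_events`, and `histogram` (data frame with
#'   `lower`, `upper` bin edges in keV/um and normalised `dose_weight`).
#' @export
score_let <- function(events, bins = 100) {
  ev <- .as_track_steps(events)
  if (nrow(ev) == 0L || sum(ev$epsilon_keV) <= 0) {
    stop("no signal: event stream is empty or deposits no energy")
  }
  eps <- ev$epsilon_keV
  len <- ev$length_um
  ratio <- eps / len
  let_track <- sum(eps) / sum(len)
  let_dose <- sum(eps * ratio) / sum(eps)
  pos <- eps > 0
  r <- ratio[pos]
  w <- eps[pos] / sum(eps[pos])
  lo <- min(r); hi <- max(r)
  if (hi / lo < 1 + 1e-12) {
    hist <- data.frame(lower = lo * (1 - 1e-6), upper = hi * (1 + 1e-6),
                       dose_weight = 1)
  } else {
    edges <- exp(seq(log(lo), log(hi), length.out = bins + 1))
    idx <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
    dw <- vapply(seq_len(bins), function(b) sum(w[idx == b]), numeric(1))
    hist <- data.frame(lower = edges[-(bins + 1)], upper = edges[-1],
                       dose_weight = dw)
  }
  structure(list(let_track = let_track, let_dose = let_dose,
                 n_events = nrow(ev), histogram = hist),
            class = "let_result")
}

#' @export
print.let_result <- function(x, ...) {
  cat(sprintf("<let_result> %d steps: LET_t = %.3f, LET_d = %.3f keV/um\n",
              x$n_events, x$let_track, x$let_dose))
  invisible(x)
}

#' Statistical uncertainty of the dose-averaged LET
#'
#' Batch-means estimator: the stream is split into `batches` contiguous
#' batches, LET_d is scored per batch, and the relative uncertainty of
#' the overall LET_d is the standard error of the batch means divided
#' by the overall value. For i.i.d. streams this scales as 1/sqrt(N).
#'
#' @param events A [track_steps()] stream.
#' @param batches Number of batches (>= 2).
#' @return Relative uncertainty (non-negative fraction).
#' @export
let_uncertainty <- function(events, batches = 10) {
  ev <- .as_track_steps(events)
  if (batches < 2) stop("at least 2 batches are required")
  if (nrow(ev) < 2 * batches) {
    stop("insufficient data: need at least 2 events per batch")
  }
  idx <- cut(seq_len(nrow(ev)), breaks = batches, labels = FALSE)
  per_batch <- vapply(seq_len(batches), function(b) {
    sub <- ev[idx == b, , drop = FALSE]
    if (sum(sub$epsilon_keV) <= 0) return(NA_real_)
    score_let(sub)$let_dose
  }, numeric(1))
  per_batch <- per_batch[is.finite(per_batch)]
  if (length(per_batch) < 2) stop("insufficient data: too few batches carry dose")
  overall <- score_let(ev)$let_dose
  stats::sd(per_batch) / sqrt(length(per_batch)) / overall
}

.as_track_steps <- function(events) {
  if (inherits(events, "track_steps")) return(events)
  if (is.data.frame(events) &&
      all(c("epsilon_keV", "length_um") %in% names(events))) {
    return(track_steps(events$epsilon_keV, events$length_um))
  }
  stop("events must be a track_steps object or a data frame with columns ",
       "'epsilon_keV' and 'length_um'")
}

#' Read or write a track-step stream as CSV
#'
#' Two-column CSV dialect: `epsilon_keV`, `length_um`.
#'
#' @param path File path.
#' @param events A [track_steps()] stream (for writing).
#' @return `read_tracks_csv` returns a [track_steps()] data frame.
#' @rdname tracks-csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("epsilon_keV", "length_um") %in% names(df))) {
    stop("track CSV must have columns 'epsilon_keV' and 'length_um'")
  }
  track_steps(df$epsilon_keV, df$length_um)
}

#' @rdname tracks-csv
#' @export
write_tracks_csv <- function(events, path) {
  ev <- .as_track_steps(events)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
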