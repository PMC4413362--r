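#' Breath-hold paradigm definition
#'
#' Describes the cyclic breath-hold task: a block of natural breathing,
#' a block of visually paced breathing, then an end-expiration breath-hold,
#' repeated over the scan. The defaults give the 6-cycle, 45 s-cycle task
#' (14 s natural + 16 s paced + 15 s hold) acquired at TR = 2 s with one
#' discarded equilibration frame, i.e. 134 retained frames over 270 s.
#'
#' @param natural_s Duration of natural breathing per cycle (s).
#' @param paced_s Duration of paced breathing per cycle (s).
#' @param hold_s Duration of the end-expiration breath-hold per cycle (s).
#' @param n_cycles Number of task cycles.
#' @param tr Repetition time of the BOLD acquisition (s).
#' @param drop_first Number of initial frames discarded before analysis.
#'
#' @return An object of class `bh_paradigm`: a list with the fields above
#'   plus `cycle_s` (cycle length) and `total_s` (task duration).
#' @examples
#' p <- make_paradigm()
#' p$cycle_s            # 45
#' paradigm_n_frames(p) # 134
#' @export
make_paradigm <- function(natural_s = 14, paced_s = 16, hold_s = 15,
                          n_cycles = 6, tr = 2, drop_first = 1) {
  vals <- c(natural_s = natural_s, paced_s = paced_s, hold_s = hold_s,
            n_cycles = n_cycles, tr = tr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("paradigm timings, n_cycles and tr must all be positive")
  if (drop_first < 0) stop("drop_first must be >= 0")
  p <- list(natural_s = natural_s, paced_s = paced_s, hold_s = hold_s,
            n_cycles = as.integer(n_cycles), tr = tr,
            drop_first = as.integer(drop_first))
  p$cycle_s <- natural_s + paced_s + hold_s
  p$total_s <- p$cycle_s * p$n_cycles
  class(p) <- "bh_paradigm"
  p
}

#' @rdname make_paradigm
#' @param paradigm A `bh_paradigm` object.
#' @export
paradigm_n_frames <- function(paradigm) {
  as.integer(floor(paradigm$total_s / paradigm$tr) - paradigm$drop_first)
}

#' Frame acquisition midpoints of the retained frames (s)
#' @inheritParams paradigm_n_frames
#' @return Numeric vector of length `paradigm_n_frames(paradigm)`.
#' @export
paradigm_frame_times <- function(paradigm) {
  n <- paradigm_n_frames(paradigm)
  (paradigm$drop_first + seq_len(n) - 0.5) * paradigm$tr
}

#' Breath-hold windows of the paradigm
#' @inheritParams paradigm_n_frames
#' @return A two-column matrix of (start, end) times in seconds, one row per
#'   hold.
#' @export
paradigm_hold_windows <- function(paradigm) {
  starts <- (seq_len(paradigm$n_cycles) - 1) * paradigm$cycle_s +
    paradigm$natural_s + paradigm$paced_s
  cbind(start = starts, end = starts + paradigm$hold_s)
}

#' Read a paradigm description from a YAML file
#'
#' The file may define any of `natural_s`, `paced_s`, `hold_s`, `n_cycles`,
#' `tr`, `drop_first`; missing fields take the defaults of
#' [make_paradigm()].
#'
#' @param path Path to a YAML file.
#' @return A `bh_paradigm` object.
#' @export
read_paradigm <- function(path) {
  y <- yaml::read_yaml(path)
  keep <- intersect(names(y),
                    c("natural_s", "paced_s", "hold_s", "n_cycles",
                      "tr", "drop_first"))
  do.call(make_paradigm, y[keep])
}

#' @export
print.bh_paradigm <- function(x, ...) {
  cat(sprintf(
    "Breath-hold paradigm: %g cycles x (%g s natural + %g s paced + %g s hold)\n",
    x$n_cycles, x$natural_s, x$paced_s, x$hold_s))
  cat(sprintf("  total %g s, TR %g s, %d frames retained (first %d dropped)\n",
              x$total_s, x$tr, paradigm_n_frames(x), x$drop_first))
  invisible(x)
}
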