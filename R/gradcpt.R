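#' Construct a gradCPT trial stream
#'
#' A trial stream is the stimulus schedule of one gradCPT run: trial onsets
#' (start of each cross-fade), stimulus category (city = go, mountain =
#' no-go) and scene identity, with a constant inter-stimulus interval.
#'
#' @param category character vector, `"city"` or `"mountain"` per trial.
#' @param isi inter-stimulus interval in seconds (the cross-fade duration;
#'   0.8 for the fast task variant, 1.3 for the slow one).
#' @param scene_id identifier per trial; consecutive trials must differ.
#' @param onset optional onsets; defaults to `(k - 1) * isi`.
#' @return a `data.frame` of class `trial_stream` with columns `onset`,
#'   `category`, `scene_id` and attribute `isi`.
#' @export
trial_stream <- function(category, isi, scene_id = NULL, onset = NULL) {
  n <- length(category)
  if (n < 1) stop("empty trial stream")
  if (!all(category %in% c("city", "mountain"))) {
    stop("category must be 'city' or 'mountain'")
  }
  if (!is.numeric(isi) || isi <= 0) stop("'isi' must be a positive number")
  if (is.null(onset)) onset <- (seq_len(n) - 1) * isi
  if (n >= 2 && any(diff(onset) <= 0)) stop("onsets must be strictly increasing")
  if (is.null(scene_id)) scene_id <- seq_len(n)
  if (n >= 2 && any(scene_id[-1] == scene_id[-n])) {
    stop("consecutive trials must not repeat a scene")
  }
  out <- data.frame(onset = onset, category = category, scene_id = scene_id,
                    stringsAsFactors = FALSE)
  attr(out, "isi") <- isi
  class(out) <- c("trial_stream", "data.frame")
  out
}

#' @export
`[.trial_stream` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "isi") <- attr(x, "isi")
    class(out) <- c("trial_stream", "data.frame")
  }
  out
}

#' Image coherence at a given reaction time
#'
#' The gradCPT cross-fades scenes linearly over one inter-stimulus interval,
#' so a reaction time measured from the start of the fade maps to image
#' coherence: at `rt = isi` the current image is 100% coherent; a shorter RT
#' means the current image is still mixed with the previous one (e.g.
#' rt = 0.9 * isi gives 90% current, 10% previous), a longer RT means it is
#' already fading into the next.
#'
#' @param rt reaction time in seconds, in `[0, 2 * isi]`.
#' @param isi inter-stimulus interval in seconds.
#' @return named numeric vector: `current`, `previous`, `next.` fractions.
#' @examples
#' rt_to_coherence(0.72, 0.8)   # 90% current, 10% previous
#' @export
rt_to_coherence <- function(rt, isi) {
  if (isi <= 0) stop("'isi' must be positive")
  if (rt < 0 || rt > 2 * isi) stop("rt outside [0, 2 * isi]")
  if (rt <= isi) {
    c(current = rt / isi, previous = 1 - rt / isi, next. = 0)
  } else {
    c(current = 2 - rt / isi, previous = 0, next. = rt / isi - 1)
  }
}

# Window bounds of the unambiguous response region for trial with onset o:
# [o + 0.7 isi, o + 1.4 isi]. Presses outside every trial's window are
# "ambiguous" (before 70% coherence of the current scene, after 40%
# coherence of the following one) and are arbitrated by assign_presses().
unambiguous_trial <- function(press, onsets, isi) {
  k <- findInterval(press - 0.7 * isi, onsets)  # last trial with window start <= press
  if (k >= 1 && press <= onsets[k] + 1.4 * isi) k else NA_integer_
}

# The two trials adjacent to an ambiguous press: the one whose window ends
# before the press and the one whose window starts after it. At the run
# edges only one candidate exists.
ambiguous_candidates <- function(press, onsets, isi) {
  n <- length(onsets)
  prev <- findInterval(press - 1.4 * isi, onsets + 1e-12)  # windows already closed
  prev <- min(prev, n)
  nxt <- prev + 1L
  c(if (prev >= 1) prev else NA_integer_,
    if (nxt <= n) nxt else NA_integer_)
}

#' Assign button presses to gradCPT trials
#'
#' The iterative press-to-trial assignment: (1) presses inside a trial's
#' unambiguous window (between 70% coherence of the current scene and 40%
#' coherence of the following scene) are assigned to that trial, the trial
#' keeping the fastest when several land on it and the surplus presses
#' joining the ambiguous set (a multiple press may answer the neighboring
#' trial); (2) each remaining ambiguous press is assigned to an adjacent trial if exactly one
#' of the two has no response; if both are empty it goes to the closest
#' trial (distance to the moment of full coherence, `onset + isi`; ties to
#' the earlier trial) unless one neighbor is a mountain, which keeps the
#' benefit of the doubt and the press goes to the other; pass 2 is repeated
#' to a fixed point since an assignment can disambiguate a neighbor;
#' (3) when several presses end up on one trial the fastest is kept.
#' Trials are then classified: city with an RT is a correct commission,
#' city without an omission error, mountain with an RT a commission error,
#' mountain without a correct omission.
#'
#' @param stream a [trial_stream()].
#' @param presses numeric vector of press timestamps (seconds, ascending).
#' @return a `data.frame` of class `rt_series` with columns `onset`,
#'   `category`, `rt` (NA when no press), `classification`, `press_index`;
#'   attribute `n_unassigned` counts presses dropped by arbitration.
#' @export
assign_presses <- function(stream, presses) {
  stopifnot(inherits(stream, "trial_stream"))
  isi <- attr(stream, "isi")
  onsets <- stream$onset
  n <- nrow(stream)
  presses <- as.numeric(presses)
  if (is.unsorted(presses)) stop("presses must be sorted ascending")
  np <- length(presses)

  # candidate trials per press: matrix np x 2 (NA for missing), plus flag
  cand <- matrix(NA_integer_, nrow = np, ncol = 2)
  unamb <- rep(NA_integer_, np)
  for (p in seq_len(np)) {
    u <- unambiguous_trial(presses[p], onsets, isi)
    if (!is.na(u)) unamb[p] <- u else cand[p, ] <- ambiguous_candidates(presses[p], onsets, isi)
  }

  # assigned[t]: indices of presses currently on trial t
  assigned <- vector("list", n)
  press_done <- rep(FALSE, np)

  # pass 1: each trial keeps the fastest of its unambiguous presses; surplus
  # in-window presses (multiple presses on one trial) become ambiguous
  # between that trial and the neighbor on the press's side of full
  # coherence, and are arbitrated in pass 2
  for (t in unique(unamb[!is.na(unamb)])) {
    ps <- which(!is.na(unamb) & unamb == t)
    rts_t <- presses[ps] - onsets[t]
    keep <- ps[which.min(rts_t)]
    assigned[[t]] <- keep
    press_done[keep] <- TRUE
    for (p in setdiff(ps, keep)) {
      side <- if (presses[p] - onsets[t] >= isi) t + 1L else t - 1L
      cand[p, ] <- c(t, if (side >= 1L && side <= n) side else NA_integer_)
    }
  }

  # pass 2: iterate ambiguous arbitration to a fixed point
  has_resp <- function(t) length(assigned[[t]]) > 0
  amb <- which(!press_done)
  for (iter in seq_len(max(np, 1L))) {
    changed <- FALSE
    for (p in amb) {
      if (press_done[p]) next
      a <- cand[p, 1]; b <- cand[p, 2]
      open_a <- !is.na(a) && !has_resp(a)
      open_b <- !is.na(b) && !has_resp(b)
      target <- NA_integer_
      if (open_a && !open_b) target <- a
      if (open_b && !open_a) target <- b
      if (open_a && open_b) {
        mt_a <- stream$category[a] == "mountain"
        mt_b <- stream$category[b] == "mountain"
        if (mt_a && mt_b) {
          # both no-go: benefit of the doubt on both; press stays unassigned
          press_done[p] <- TRUE
          changed <- TRUE
          next
        } else if (mt_a) {
          target <- b
        } else if (mt_b) {
          target <- a
        } else {
          da <- abs(presses[p] - (onsets[a] + isi))
          db <- abs(presses[p] - (onsets[b] + isi))
          target <- if (db < da) b else a   # tie -> earlier trial
        }
      }
      if (!is.na(target)) {
        assigned[[target]] <- c(assigned[[target]], p)
        press_done[p] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # pass 3: fastest press per trial
  rt <- rep(NA_real_, n)
  press_index <- rep(NA_integer_, n)
  for (t in seq_len(n)) {
    ps <- assigned[[t]]
    if (length(ps) == 0) next
    rts_t <- presses[ps] - onsets[t]
    j <- which.min(rts_t)
    rt[t] <- rts_t[j]
    press_index[t] <- ps[j]
  }

  classification <- ifelse(
    stream$category == "city",
    ifelse(is.na(rt), "omission_error", "correct_commission"),
    ifelse(is.na(rt), "correct_omission", "commission_error")
  )
  out <- data.frame(
    onset = onsets, category = stream$category, rt = rt,
    classification = classification, press_index = press_index,
    stringsAsFactors = FALSE
  )
  attr(out, "isi") <- isi
  attr(out, "n_unassigned") <- np - sum(!is.na(press_index))
  class(out) <- c("rt_series", "data.frame")
  out
}

#' Accuracy counts for an assigned run
#'
#' @param rts an `rt_series` from [assign_presses()].
#' @return list with `omission`, `commission`, `correct_commission`,
#'   `correct_omission` counts and `omission_rate` / `commission_rate`
#'   (denominators: city and mountain trials respectively).
#' @export
error_counts <- function(rts) {
  cls <- rts$classification
  n_city <- sum(rts$category == "city")
  n_mountain <- sum(rts$category == "mountain")
  om <- sum(cls == "omission_error")
  co <- sum(cls == "commission_error")
  list(
    omission = om,
    commission = co,
    correct_commission = sum(cls == "correct_commission"),
    correct_omission = sum(cls == "correct_omission"),
    omission_rate = if (n_city > 0) om / n_city else NA_real_,
    commission_rate = if (n_mountain > 0) co / n_mountain else NA_real_
  )
}

#' Tune-out detection
#'
#' Flags a run (participant) containing an interval of `window` seconds or
#' more without any assigned response, counting the gaps from run start to
#' the first response and from the last response to run end. Flagged
#' participants are excluded from population analyses.
#'
#' @param rts an `rt_series`.
#' @param window gap threshold in seconds (default 30; the boundary counts:
#'   a gap of exactly `window` flags).
#' @param run_end run duration in seconds; defaults to the last trial's
#'   onset plus one ISI.
#' @return logical flag.
#' @export
exclude_tuneouts <- function(rts, window = 30, run_end = NULL) {
  isi <- attr(rts, "isi")
  if (is.null(run_end)) run_end <- max(rts$onset) + (isi %||% 0)
  times <- sort(rts$onset[!is.na(rts$rt)] + rts$rt[!is.na(rts$rt)])
  gaps <- diff(c(0, times, run_end))
  any(gaps >= window)
}
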