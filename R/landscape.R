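#' Canonical eight-network names
#'
#' The cortical networks used in the eight-network analysis: default mode,
#' limbic, the two frontoparietal subsystems, dorsal attention, salience,
#' somato-motor and visual.
#' @export
gradstate_networks <- c("DMN", "Limbic", "FPN_A", "FPN_B",
                        "DAN", "SN", "SMN", "Visual")

# neighbor codes (Hamming distance 1) for every pattern code, (2^N x N)
neighbor_codes <- function(N) {
  codes <- 0:(2^N - 1)
  vapply(seq_len(N), function(i) bitwXor(codes, bitwShiftL(1L, i - 1L)),
         integer(2^N))
}

#' Local minima of an energy landscape
#'
#' A pattern is a local minimum when its energy is strictly smaller than
#' the energies of all N adjacent patterns (patterns differing in exactly
#' one unit). Ties disqualify: a pattern sharing its lowest-neighborhood
#' energy with a neighbor is not a minimum.
#'
#' @param energies numeric vector of length 2^N, indexed by pattern
#'   code + 1.
#' @return integer vector of minimum pattern codes (0-based).
#' @export
find_minima <- function(energies) {
  N <- round(log2(length(energies)))
  if (2^N != length(energies)) stop("length must be a power of two")
  nb <- neighbor_codes(N)
  emat <- matrix(energies[nb + 1L], nrow = length(energies))
  which(energies < apply(emat, 1, min)) - 1L
}

#' Basin assignment by steepest descent
#'
#' From every pattern, repeatedly move to the neighbor with the smallest
#' energy as long as some neighbor is strictly lower; the minimum reached
#' defines the pattern's basin. Ties among equally smallest lower
#' neighbors break to the lowest pattern code, making the map
#' deterministic.
#'
#' @param energies numeric vector of length 2^N.
#' @return integer vector of length 2^N: basin minimum code (0-based) per
#'   pattern code.
#' @export
basin_assign <- function(energies) {
  N <- round(log2(length(energies)))
  if (2^N != length(energies)) stop("length must be a power of two")
  K <- length(energies)
  nb <- neighbor_codes(N)
  # next step of steepest descent per pattern (NA at minima)
  nxt <- rep(NA_integer_, K)
  for (k in seq_len(K)) {
    nbk <- nb[k, ]
    en <- energies[nbk + 1L]
    j <- which(en == min(en))
    best <- nbk[j][which.min(nbk[j])]   # tie -> lowest pattern code
    if (energies[best + 1L] < energies[k]) nxt[k] <- best
  }
  basin <- rep(NA_integer_, K)
  ord <- order(energies)                # strict descent => target resolved first
  for (k in ord) {
    basin[k] <- if (is.na(nxt[k])) k - 1L else basin[nxt[k] + 1L]
  }
  if (anyNA(basin)) stop("internal error: descent failed to resolve a basin")
  basin
}

#' Exhaustive energy-landscape analysis of a fitted model
#'
#' Enumerates the energies and Boltzmann probabilities of all 2^N activity
#' patterns, locates the local minima (the brain states) and assigns every
#' pattern to a minimum by steepest descent.
#'
#' @param model a [mem_model()] with N <= 16.
#' @return object of class `energy_landscape`: list with `energies`,
#'   `probabilities`, `minima` (pattern codes, 0-based), `basin` (length
#'   2^N), `networks`, `N`.
#' @export
energy_landscape <- function(model) {
  e <- all_energies(model)
  structure(list(
    energies = e,
    probabilities = pattern_probabilities(model),
    minima = find_minima(e),
    basin = basin_assign(e),
    networks = model$networks,
    N = model$N
  ), class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("energy landscape over %d patterns (%d units)\n", 2^x$N, x$N))
  lab <- label_named_states(x)
  for (m in x$minima) {
    act <- x$networks[decode_pattern(m, x$N) == 1]
    cat(sprintf("  minimum %d [%s]: E = %.3f, P(basin) = %.3f, active: %s\n",
                m, lab[as.character(m)], x$energies[m + 1],
                sum(x$probabilities[x$basin == m]),
                if (length(act)) paste(act, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

decode_pattern <- function(code, N) {
  bitwAnd(bitwShiftR(code, 0:(N - 1)), 1L)
}

#' Name landscape minima by their dominant-network template
#'
#' State1 is the minimum dominated by active FPN_A, DMN and limbic
#' networks; State2 the one dominated by active FPN_B, DAN, SN, SMN and
#' visual networks. A minimum earns a label when a strict majority of the
#' template's networks are active in the pattern and a strict majority of
#' the opposite template's networks are inactive; anything else (including
#' patterns matching both templates) is labelled `"other"`.
#'
#' @param landscape an [energy_landscape()] whose `networks` use the
#'   [gradstate_networks] names (extra or missing names demote every
#'   minimum to `"other"`).
#' @return named character vector, one label per minimum, names = pattern
#'   codes.
#' @export
label_named_states <- function(landscape) {
  nets <- landscape$networks
  t1 <- c("FPN_A", "DMN", "Limbic")
  t2 <- c("FPN_B", "DAN", "SN", "SMN", "Visual")
  i1 <- match(t1, nets)
  i2 <- match(t2, nets)
  labs <- vapply(landscape$minima, function(m) {
    if (anyNA(i1) || anyNA(i2)) return("other")
    bits <- decode_pattern(m, landscape$N)
    maj1 <- sum(bits[i1] == 1) > length(t1) / 2 &&
      sum(bits[i2] == 0) > length(t2) / 2
    maj2 <- sum(bits[i2] == 1) > length(t2) / 2 &&
      sum(bits[i1] == 0) > length(t1) / 2
    if (maj1 && !maj2) "State1" else if (maj2 && !maj1) "State2" else "other"
  }, character(1))
  names(labs) <- landscape$minima
  labs
}

#' Per-volume brain-state series with hemodynamic-lag alignment
#'
#' Maps each volume's binarized activity pattern to its basin minimum and
#' shifts the resulting state labels backwards in time by
#' `round(lag / tr)` volumes (exact halves round down), so that the state
#' label aligned with behavioral time t is taken from the volume acquired
#' about one hemodynamic delay later.
#'
#' @param binary 0/1 matrix, T x N, one run.
#' @param landscape an [energy_landscape()].
#' @param tr repetition time in seconds.
#' @param lag hemodynamic lag in seconds (default 5).
#' @return object of class `state_series`: list with `state` (integer
#'   minimum codes, length T - shift), `shift_volumes`, `tr`, `lag`.
#' @export
state_series <- function(binary, landscape, tr, lag = 5) {
  if (tr <= 0) stop("'tr' must be positive")
  binary <- as.matrix(binary)
  shift <- as.integer(ceiling(lag / tr - 0.5))  # .5 rounds down
  Tn <- nrow(binary)
  if (Tn <= shift) stop("run shorter than the hemodynamic shift")
  codes <- patterns_to_codes(binary)
  states <- landscape$basin[codes + 1L]
  structure(list(
    state = states[(shift + 1L):Tn],
    shift_volumes = shift, tr = tr, lag = lag
  ), class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat(sprintf("state series: %d volumes (tr = %.3g s, shifted back %d volumes)\n",
              length(x$state), x$tr, x$shift_volumes))
  print(table(x$state))
  invisible(x)
}
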