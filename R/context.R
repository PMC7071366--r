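# Context integration: weight, perturb and depth-stack a target stimulus
# with its flanking context stimuli into the classifier input cuboid.
#
# With span S = S1 + S2 context stimuli (S1 to the left, S2 to the right)
# each slot i in -S1..S2 contributes the slice
#     alpha_i * pixels_i + N(0, sigma2_i)  (elementwise, fresh noise)
# and slices are stacked along the z (channel) axis in increasing i, so
# the most distant left context comes first and the target sits at i = 0.
# S = 0 recovers the plain context-free classifier input.

#' Configuration of the context-integration operator
#'
#' @param S1,S2 Number of context stimuli to the left / right of the target
#'   (non-negative integers). The span is `S = S1 + S2`; `S1 == S2` gives a
#'   symmetric model.
#' @param weights Vector of coupling weights, length `S1 + 1 + S2`, ordered
#'   by slot position `-S1 .. S2` (the entry at position 0 weights the
#'   target). All weights must lie in `[0, 1]`: 0 removes a stimulus from
#'   the input, 1 passes it at full strength. Default: all 1.
#' @param noise_variances Per-slot Gaussian noise variances, same length and
#'   ordering, all `>= 0`. Default: all 0.
#' @return An `integration_config` object.
#' @examples
#' cfg <- integration_config(S1 = 1, S2 = 1)
#' cfg$span
#' @export
integration_config <- function(S1, S2, weights = NULL, noise_variances = NULL) {
  if (S1 < 0 || S2 < 0 || S1 != round(S1) || S2 != round(S2)) {
    stop("'S1' and 'S2' must be non-negative integers")
  }
  n <- S1 + 1 + S2
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(noise_variances)) noise_variances <- rep(0, n)
  if (length(weights) != n) {
    stop(sprintf("'weights' must have length S1 + 1 + S2 = %d", n))
  }
  if (any(weights < 0 | weights > 1)) stop("all weights must lie in [0, 1]")
  if (length(noise_variances) != n) {
    stop(sprintf("'noise_variances' must have length S1 + 1 + S2 = %d", n))
  }
  if (any(noise_variances < 0)) stop("all noise variances must be >= 0")
  positions <- seq.int(-S1, S2)
  structure(
    list(S1 = as.integer(S1), S2 = as.integer(S2), span = as.integer(S1 + S2),
         positions = positions, weights = as.numeric(weights),
         noise_variances = as.numeric(noise_variances)),
    class = "integration_config"
  )
}

slice_depth <- function(px) if (is.matrix(px)) 1L else dim(px)[3L]

#' Stack target and context stimuli into a classifier input cuboid
#'
#' Applies the per-slot weight, adds fresh per-slot Gaussian noise, and
#' depth-stacks the slices in slot order `-S1 .. S2`. Stimuli of z-depth
#' `Z` produce a cuboid of depth `Z * (1 + S1 + S2)`; for 2-d letter
#' glyphs (`Z = 1`) with span `S` that is `H x W x (1 + S)`. No mixing
#' occurs across slices: slot `i` of the output depends only on stimulus
#' `i`.
#'
#' @param target Target stimulus (glyph, noisy stimulus, matrix or array).
#' @param left_context List of `S1` stimuli, most distant first.
#' @param right_context List of `S2` stimuli, nearest first.
#' @param config An [integration_config()].
#' @param seed Optional integer seed for the per-slot noise streams.
#' @return An `integrated_input`: list with `cuboid` (H x W x depth array)
#'   and `slot_labels` (data frame of position, role, label per slice).
#' @examples
#' cfg <- integration_config(1, 1)
#' x <- integrate_stimuli(render_glyph("A"),
#'                        list(render_glyph("B")), list(render_glyph("G")), cfg)
#' dim(x$cuboid)
#' @export
integrate_stimuli <- function(target, left_context = list(), right_context = list(),
                              config, seed = NULL) {
  stopifnot(inherits(config, "integration_config"))
  if (length(left_context) != config$S1) {
    stop(sprintf("expected %d left context stimuli, got %d",
                 config$S1, length(left_context)))
  }
  if (length(right_context) != config$S2) {
    stop(sprintf("expected %d right context stimuli, got %d",
                 config$S2, length(right_context)))
  }
  stims <- c(left_context, list(target), right_context)
  pxs <- lapply(stims, stimulus_pixels)
  hw <- dim(pxs[[1L]])[1:2]
  Z <- slice_depth(pxs[[1L]])
  for (p in pxs) {
    if (!identical(dim(p)[1:2], hw) || slice_depth(p) != Z) {
      stop("all stimuli must share height, width and z-depth")
    }
  }
  n <- length(stims)
  depth <- Z * n
  cuboid <- array(0, dim = c(hw[1L], hw[2L], depth))
  for (k in seq_len(n)) {
    px <- config$weights[k] * pxs[[k]]
    s2 <- config$noise_variances[k]
    if (s2 > 0) {
      slot_seed <- if (is.null(seed)) NULL else derive_seed(seed, "slot", k)
      px <- px + array(local_rnorm(length(px), sd = sqrt(s2), seed = slot_seed),
                       dim = dim(px))
    }
    cuboid[, , (k - 1L) * Z + seq_len(Z)] <- px
  }
  roles <- c(rep("context", config$S1), "target", rep("context", config$S2))
  labels <- vapply(stims, function(s) {
    if (inherits(s, "glyph")) s$label
    else if (inherits(s, "noisy_stimulus") && inherits(s$source, "glyph")) s$source$label
    else ""
  }, character(1L))
  structure(
    list(cuboid = cuboid,
         slot_labels = data.frame(position = config$positions, role = roles,
                                  label = labels, stringsAsFactors = FALSE)),
    class = "integrated_input"
  )
}

#' Build a classifier input from a word with a substituted centre stimulus
#'
#' Renders the letters of `word` as glyph fixtures, replaces the middle
#' letter with `center_stimulus` (for example a noisy ambiguous hybrid),
#' and integrates them under `config`. The word length must equal
#' `S1 + 1 + S2`.
#'
#' @param word Upper-case letter string, e.g. `"BAG"` for a span-2 model
#'   (B and G are the context of centre letter A).
#' @param center_stimulus Stimulus to place at the centre slot; default is
#'   the word's own middle letter glyph.
#' @param config An [integration_config()].
#' @param seed Optional integer seed, passed to [integrate_stimuli()].
#' @return An `integrated_input`.
#' @examples
#' cfg <- integration_config(1, 1)
#' x <- word_input("BAG", config = cfg)
#' x$slot_labels
#' @export
word_input <- function(word, center_stimulus = NULL, config, seed = NULL) {
  stopifnot(inherits(config, "integration_config"))
  letters_ <- strsplit(word, "")[[1L]]
  n <- config$S1 + 1L + config$S2
  if (length(letters_) != n) {
    stop(sprintf("word '%s' has %d letters but the span requires %d",
                 word, length(letters_), n))
  }
  mid <- config$S1 + 1L
  if (is.null(center_stimulus)) center_stimulus <- render_glyph(letters_[mid])
  left <- lapply(letters_[seq_len(config$S1)], render_glyph)
  right <- if (config$S2 > 0) {
    lapply(letters_[mid + seq_len(config$S2)], render_glyph)
  } else list()
  integrate_stimuli(center_stimulus, left, right, config, seed = seed)
}

#' Exchange the left and right context of a word
#'
#' `"BAG"` becomes `"GAB"`: the word is mirrored about its centre letter,
#' which preserves the letter identities but destroys the spatial pattern
#' learned during training.
#'
#' @param word Upper-case letter string of odd length.
#' @return The flipped word.
#' @examples
#' flip_word("BEAST")
#' @export
flip_word <- function(word) {
  letters_ <- strsplit(word, "")[[1L]]
  if (length(letters_) %% 2L == 0L) stop("flip_word requires an odd word length")
  paste(rev(letters_), collapse = "")
}

#' @export
print.integration_config <- function(x, ...) {
  cat(sprintf("<integration_config S1=%d S2=%d span=%d>\n", x$S1, x$S2, x$span))
  cat("  weights:        ", paste(format(x$weights), collapse = " "), "\n")
  cat("  noise variances:", paste(format(x$noise_variances), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.integrated_input <- function(x, ...) {
  d <- dim(x$cuboid)
  cat(sprintf("<integrated_input %d x %d x %d [%s]>\n", d[1], d[2], d[3],
              paste(x$slot_labels$label, collapse = " ")))
  invisible(x)
}
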