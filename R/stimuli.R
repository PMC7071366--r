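# Glyph fixtures and stimulus perturbation.
#
# All visual stimuli are 32 x 32 binary arrays: block-capital letter glyphs
# shipped as text fixtures under extdata/glyphs, plus three hand-designed
# ambiguous hybrids ([A/H], [O/U], [P/R]) that sit near-equidistant (in
# Hamming distance) between their two parent letters.

.glyph_cache <- new.env(parent = emptyenv())

glyph_dir <- function() {
  system.file("extdata", "glyphs", package = "ctxnet", mustWork = TRUE)
}

glyph_manifest <- function() {
  if (is.null(.glyph_cache$manifest)) {
    .glyph_cache$manifest <- utils::read.csv(
      file.path(glyph_dir(), "manifest.csv"),
      stringsAsFactors = FALSE, colClasses = "character"
    )
  }
  .glyph_cache$manifest
}

read_glyph_file <- function(path) {
  lines <- readLines(path)
  px <- do.call(rbind, lapply(strsplit(lines, ""), function(ch) as.integer(ch == "#")))
  storage.mode(px) <- "double"
  px
}

new_glyph <- function(pixels, label, role, parents = NULL) {
  stopifnot(is.matrix(pixels), all(pixels %in% c(0, 1)))
  n_fg <- sum(pixels)
  if (n_fg <= 0 || n_fg >= length(pixels)) {
    stop("glyph must contain both foreground and background pixels")
  }
  g <- structure(
    list(pixels = pixels, label = label, role = role),
    class = "glyph"
  )
  if (!is.null(parents)) {
    g$parents <- parents
    class(g) <- c("ambiguous_glyph", "glyph")
  }
  g
}

#' Letters available as glyph fixtures
#'
#' @return Character vector of letters with a shipped 32 x 32 bitmap.
#' @export
glyph_letters <- function() {
  m <- glyph_manifest()
  m$name[m$role %in% c("target", "context")]
}

#' The six target letters
#'
#' The letter classes the classifiers are trained on, in class-index order.
#'
#' @return Character vector `c("A","H","O","U","P","R")`.
#' @export
target_letters <- function() c("A", "H", "O", "U", "P", "R")

#' Retrieve a letter glyph
#'
#' Returns the fixture bitmap for an upper-case letter as a binary
#' 32 x 32 matrix (1 = foreground). Retrieval is deterministic: the same
#' letter always yields a bit-identical glyph.
#'
#' @param letter Single upper-case letter.
#' @return A `glyph` object with fields `pixels` (32 x 32 binary matrix),
#'   `label` and `role` (`"target"` for the six trained classes, otherwise
#'   `"context"`).
#' @examples
#' g <- render_glyph("A")
#' dim(g$pixels)
#' @export
render_glyph <- function(letter) {
  if (!is.character(letter) || length(letter) != 1L || nchar(letter) != 1L) {
    stop("'letter' must be a single character")
  }
  key <- paste0("g_", letter)
  if (!is.null(.glyph_cache[[key]])) return(.glyph_cache[[key]])
  m <- glyph_manifest()
  row <- m[m$name == letter & m$role != "ambiguous", , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no glyph fixture for letter '%s'", letter))
  }
  px <- read_glyph_file(file.path(glyph_dir(), row$file[1L]))
  g <- new_glyph(px, letter, row$role[1L])
  .glyph_cache[[key]] <- g
  g
}

#' Retrieve an ambiguous hybrid glyph
#'
#' An ambiguous glyph admits two mutually exclusive interpretations: it is
#' constructed to lie near-equidistant (Hamming distance on pixels) between
#' its two parent letters, and strictly closer to either parent than to any
#' other target letter. Hybrids ship as hand-designed fixtures for the pairs
#' (A,H), (O,U) and (P,R).
#'
#' @param parent1,parent2 The two parent target letters (order free).
#' @return An `ambiguous_glyph` with fields `pixels`, `label` (e.g. `"A/H"`)
#'   and `parents` (character vector of length 2, fixture order).
#' @examples
#' h <- make_ambiguous("A", "H")
#' h$parents
#' @export
make_ambiguous <- function(parent1, parent2) {
  tl <- target_letters()
  if (!parent1 %in% tl || !parent2 %in% tl) {
    stop("both parents must be target letters (A, H, O, U, P, R)")
  }
  if (parent1 == parent2) stop("degenerate pair: parents must differ")
  key <- paste(sort(c(parent1, parent2)), collapse = "")
  m <- glyph_manifest()
  row <- m[m$role == "ambiguous" & m$parents == key, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no hybrid fixture for parent pair (%s, %s)", parent1, parent2))
  }
  ck <- paste0("h_", key)
  if (!is.null(.glyph_cache[[ck]])) return(.glyph_cache[[ck]])
  px <- read_glyph_file(file.path(glyph_dir(), row$file[1L]))
  parents <- strsplit(row$parents[1L], "")[[1L]]
  g <- new_glyph(px, paste(parents, collapse = "/"), "ambiguous", parents = parents)
  .glyph_cache[[ck]] <- g
  g
}

#' Hamming distance between two stimuli
#'
#' Number of pixels at which two binary bitmaps differ.
#'
#' @param a,b Glyphs or binary matrices of identical shape.
#' @return Integer count of differing pixels.
#' @export
hamming_distance <- function(a, b) {
  pa <- stimulus_pixels(a)
  pb <- stimulus_pixels(b)
  stopifnot(identical(dim(pa), dim(pb)))
  sum(pa != pb)
}

#' Extract the pixel array from any stimulus representation
#'
#' @param x A `glyph`, `noisy_stimulus`, matrix or 3-d array.
#' @return Numeric matrix (H x W) or array (H x W x Z).
#' @export
stimulus_pixels <- function(x) {
  if (inherits(x, "glyph")) return(x$pixels)
  if (inherits(x, "noisy_stimulus")) return(x$pixels)
  if (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)) return(x)
  stop("cannot interpret object as a stimulus")
}

#' Corrupt a stimulus with additive Gaussian pixel noise
#'
#' Adds independent zero-mean Gaussian noise of the given variance to every
#' pixel (foreground and background alike). Outputs are unclipped real
#' values; with variance 0 the stimulus is returned unchanged. Increasing
#' the variance is the mechanism used to raise the ambiguity level of a
#' test stimulus.
#'
#' @param stimulus A `glyph`, `ambiguous_glyph` or numeric matrix.
#' @param variance Noise variance, a single number `>= 0`.
#' @param seed Optional integer; when given, draws come from a private
#'   seeded stream and the call is reproducible without disturbing the
#'   caller's RNG state.
#' @return A `noisy_stimulus` with fields `pixels` (real matrix), `source`,
#'   `variance` and `seed`.
#' @examples
#' n <- add_noise(render_glyph("A"), variance = 0.5, seed = 1)
#' @export
add_noise <- function(stimulus, variance, seed = NULL) {
  if (!is.numeric(variance) || length(variance) != 1L || is.na(variance) || variance < 0) {
    stop("'variance' must be a single non-negative number")
  }
  px <- stimulus_pixels(stimulus)
  if (variance > 0) {
    noise <- local_rnorm(length(px), sd = sqrt(variance), seed = seed)
    px <- px + array(noise, dim = dim(px))
  }
  structure(
    list(pixels = px, source = stimulus, variance = variance, seed = seed),
    class = "noisy_stimulus"
  )
}

# Draw n N(0, sd^2) deviates, optionally from a private seeded stream that
# leaves the caller's .Random.seed untouched.
local_rnorm <- function(n, sd, seed = NULL) {
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

# Deterministic 31-bit sub-seed derivation, so that independent noise
# streams (per network, per replicate, per slot) never collide by accident.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_len(nchar(p))) else as.numeric(p)
    h <- (h * 69069 + v + 1) %% 2147483647
  }
  as.integer(h)
}

#' @export
print.glyph <- function(x, ...) {
  cat(sprintf("<glyph '%s' (%s), %d x %d, %d foreground px>\n",
              x$label, x$role, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
print.noisy_stimulus <- function(x, ...) {
  src <- if (inherits(x$source, "glyph")) x$source$label else "array"
  cat(sprintf("<noisy_stimulus of '%s', sigma^2 = %g>\n", src, x$variance))
  invisible(x)
}

#' Render a stimulus as ASCII art (debugging aid)
#'
#' @param x A stimulus; values are thresholded at 0.5 for display.
#' @param ... Unused.
#' @export
glyph_ascii <- function(x, ...) {
  px <- stimulus_pixels(x)
  apply(px, 1, function(r) paste(ifelse(r > 0.5, "#", "."), collapse = ""))
}
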