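GLYPH_NAMES <- c("bird", "cat", "seeds", "blank")
WORD_NAMES <- c("flee", "feed", "wait")

#' Procedurally generate the pictogram glyphs
#'
#' Deterministic 32 x 32 grayscale images (values in `[0, 1]`) for the four
#' letter categories bird, cat, seeds and blank. The three non-blank shapes
#' are drawn to be discriminable: all pairwise normalized cross-correlations
#' are below 0.5. The blank glyph is all zeros (an empty quadrant is an
#' explicit outcome: seeing nothing is evidence).
#'
#' @param seed Seed for the (deterministic) dot placement of the seeds
#'   glyph; the same seed always yields identical images.
#' @return Named list of four 32 x 32 matrices.
#' @export
make_glyphs <- function(seed = 1L) {
  n <- 32L
  u <- matrix(rep((seq_len(n) - (n + 1) / 2) / (n / 2), n), n, n)          # x in [-1,1]
  v <- matrix(rep((seq_len(n) - (n + 1) / 2) / (n / 2), each = n), n, n)   # y in [-1,1]

  # bird: an annulus (body) with a beak wedge
  r2 <- u^2 + v^2
  bird <- (r2 < 0.55^2 & r2 > 0.28^2) * 1
  bird[u > 0.45 & abs(v) < (0.75 - u) * 0.4 & u < 0.9] <- 1

  # cat: a filled triangle (face) with two ear spikes
  cat_img <- (v < 0.35 & v > -0.5 & abs(u) < (0.35 - v) * 0.55) * 1
  cat_img[v >= 0.3 & v < 0.8 & (abs(u - 0.35) < 0.1 | abs(u + 0.35) < 0.1)] <- 1

  # seeds: a scatter of small dots
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  centers <- cbind(stats::runif(16, -0.75, 0.75), stats::runif(16, -0.75, 0.75))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  seeds <- matrix(0, n, n)
  for (i in seq_len(nrow(centers))) {
    seeds[(u - centers[i, 1])^2 + (v - centers[i, 2])^2 < 0.14^2] <- 1
  }

  list(bird = bird, cat = cat_img, seeds = seeds, blank = matrix(0, n, n))
}

# normalized cross-correlation between two images (zero-mean)
glyph_ncc <- function(a, b) {
  a <- as.numeric(a) - mean(a)
  b <- as.numeric(b) - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# 4 x 4 block-mean features of a 32 x 32 glyph (16-vector in [0, 1])
glyph_features <- function(img, blocks = 4L) {
  n <- nrow(img)
  sz <- n / blocks
  f <- numeric(blocks^2)
  k <- 1L
  for (j in seq_len(blocks)) {
    for (i in seq_len(blocks)) {
      f[k] <- mean(img[(i - 1) * sz + seq_len(sz), (j - 1) * sz + seq_len(sz)])
      k <- k + 1L
    }
  }
  f
}

# quadrant -> glyph index table for every word x vflip x hflip combination.
# Quadrants are 1 = upper-left, 2 = upper-right, 3 = lower-left,
# 4 = lower-right. flee: bird next to cat; feed: bird next to seeds;
# wait: seeds above (or below) the bird.
word_layouts <- function() {
  base <- list(
    flee = c(1L, 2L, 4L, 4L),   # bird, cat, blank, blank
    feed = c(1L, 3L, 4L, 4L),   # bird, seeds, blank, blank
    wait = c(3L, 4L, 1L, 4L)    # seeds above bird
  )
  vswap <- c(3L, 4L, 1L, 2L)   # swap rows
  hswap <- c(2L, 1L, 4L, 3L)   # swap columns
  out <- array(0L, c(3L, 2L, 2L, 4L),
               dimnames = list(WORD_NAMES, c("v0", "v1"), c("h0", "h1"), NULL))
  for (w in 1:3) {
    for (vf in 1:2) {
      for (hf in 1:2) {
        lay <- base[[w]]
        if (vf == 2L) lay <- lay[vswap]
        if (hf == 2L) lay <- lay[hswap]
        out[w, vf, hf, ] <- lay
      }
    }
  }
  out
}

default_sentences <- function() {
  # 6 sentences x 4 words; sentences 1 and 4 share words 1-3 and are only
  # disambiguated by the final word
  matrix(c(
    1L, 2L, 3L, 2L,   # flee feed wait feed
    2L, 3L, 1L, 1L,   # feed wait flee flee
    3L, 1L, 2L, 3L,   # wait flee feed wait
    1L, 2L, 3L, 3L,   # flee feed wait wait
    2L, 1L, 3L, 2L,   # feed flee wait feed
    3L, 2L, 1L, 1L    # wait feed flee flee
  ), nrow = 6L, byrow = TRUE)
}

#' Build the pictographic reading environment
#'
#' The synthetic world: six sentences of four words over
#' \{flee, feed, wait\}, the quadrant layout of each word under vertical and
#' horizontal flips, procedurally generated 32 x 32 glyph images, the four
#' quadrant target locations and the Gaussian contrast-attenuation width.
#' The generating configuration (`true_sentence`, `true_flips`) lives on the
#' process side.
#'
#' @param sentences Integer matrix `6 x 4` of word indices (1 = flee,
#'   2 = feed, 3 = wait).
#' @param attenuation_sigma Width of the Gaussian contrast attenuation, in
#'   gaze units (quadrant width = 1).
#' @param true_sentence Generating sentence index.
#' @param true_flips Integer pair (vertical, horizontal flip states in
#'   1:2).
#' @param glyph_seed Seed for [make_glyphs()].
#' @return Object of class `reading_world`.
#' @export
reading_world <- function(sentences = default_sentences(),
                          attenuation_sigma = 0.35,
                          true_sentence = 1L, true_flips = c(1L, 1L),
                          glyph_seed = 1L) {
  stopifnot(nrow(sentences) == 6L, ncol(sentences) == 4L,
            all(sentences %in% 1:3))
  glyphs <- make_glyphs(glyph_seed)
  structure(list(
    sentences = sentences,
    word_layouts = word_layouts(),
    glyphs = glyphs,
    features = lapply(glyphs, glyph_features),
    quadrant_centers = matrix(c(-0.5, 0.5, 0.5, 0.5, -0.5, -0.5, 0.5, -0.5),
                              4L, 2L, byrow = TRUE),
    attenuation_sigma = attenuation_sigma,
    true_sentence = as.integer(true_sentence),
    true_flips = as.integer(true_flips)
  ), class = "reading_world")
}

#' @export
print.reading_world <- function(x, ...) {
  cat(sprintf("<reading_world: 6 sentences x 4 words, true sentence %d, sigma = %.3g>\n",
              x$true_sentence, x$attenuation_sigma))
  invisible(x)
}

#' Eccentric, contrast-attenuated visual sample
#'
#' Returns the glyph image shifted by the displacement `d = target - gaze`
#' and multiplied by the Gaussian contrast factor
#' `exp(-||d||^2 / (2 sigma^2))`: sensory attenuation means high-contrast
#' input is only available at fixation. At `d = 0` the glyph is returned
#' unshifted and unattenuated.
#'
#' @param world A [reading_world()].
#' @param glyph Glyph index (1-4) or name.
#' @param gaze,target Two-dimensional gaze and target locations.
#' @return 32 x 32 matrix (the observed patch).
#' @export
sample_visual <- function(world, glyph, gaze, target) {
  if (is.character(glyph)) glyph <- match(glyph, GLYPH_NAMES)
  if (any(!is.finite(c(gaze, target)))) stopf("sample_visual: non-finite gaze/target")
  img <- world$glyphs[[glyph]]
  d <- target - gaze
  contrast <- exp(-sum(d^2) / (2 * world$attenuation_sigma^2))
  n <- nrow(img)
  px <- round(d * (n / 2))
  out <- matrix(0, n, n)
  # shift: pixel (i, j) of the output samples the glyph at (i - px_y, j - px_x)
  src_i <- seq_len(n) - px[2L]
  src_j <- seq_len(n) - px[1L]
  ok_i <- which(src_i >= 1 & src_i <= n)
  ok_j <- which(src_j >= 1 & src_j <= n)
  if (length(ok_i) && length(ok_j)) {
    out[ok_i, ok_j] <- img[src_i[ok_i], src_j[ok_j]]
  }
  out * contrast
}
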