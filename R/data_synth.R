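#' Specification of a synthetic multi-class pattern task
#'
#' Describes a family of grayscale prototype patterns with sparse foreground
#' on a zero background — the structural regime the unsupervised pipeline
#' relies on (most pixels inactive, a minority driven hard) — plus i.i.d.
#' per-pixel "flip" noise applied when sampling: foreground pixels drop to 0
#' and background pixels jump to `fg_intensity`, each with probability
#' `flip_prob`.
#'
#' @param n_classes Number of classes.
#' @param height,width Image dimensions in pixels.
#' @param fg_intensity Foreground pixel value (8-bit scale by default).
#' @param flip_prob Per-pixel noise probability, in `[0, 0.5)`.
#' @param n_train,n_test Sample counts for the train/test splits.
#' @param seed Integer seed; prototypes and samples are reproducible.
#'
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_classes = 5, height = 10, width = 10,
                           fg_intensity = 255, flip_prob = 0.1,
                           n_train = 3000, n_test = 1000, seed = 1) {
  if (flip_prob < 0 || flip_prob >= 0.5) {
    stop("`flip_prob` must be in [0, 0.5)", call. = FALSE)
  }
  if (n_classes < 2) stop("need at least 2 classes", call. = FALSE)
  structure(
    list(n_classes = n_classes, height = height, width = width,
         fg_intensity = fg_intensity, flip_prob = flip_prob,
         n_train = n_train, n_test = n_test, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate class prototype patterns
#'
#' Each prototype is a `height x width` matrix with a random foreground
#' support (20-40% of pixels at `fg_intensity`, the rest exactly 0).
#' Prototypes of distinct classes are rejected and redrawn until every pair
#' differs in at least 25% of pixels, so classes are well separated.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param max_tries Redraw budget before giving up on the separation
#'   constraint.
#'
#' @return A list of `n_classes` integer matrices.
#' @export
make_prototypes <- function(spec, max_tries = 1000) {
  set.seed(spec$seed)
  n_pix <- spec$height * spec$width
  min_dist <- ceiling(0.25 * n_pix)
  draw <- function() {
    frac <- stats::runif(1, 0.2, 0.4)
    support <- sample.int(n_pix, size = round(frac * n_pix))
    m <- matrix(0, spec$height, spec$width)
    m[support] <- spec$fg_intensity
    m
  }
  protos <- list(draw())
  tries <- 0L
  while (length(protos) < spec$n_classes) {
    cand <- draw()
    dists <- vapply(protos, function(p) sum(p != cand), integer(1))
    if (all(dists >= min_dist)) {
      protos[[length(protos) + 1L]] <- cand
    } else {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not satisfy the prototype separation constraint",
             call. = FALSE)
      }
    }
  }
  protos
}

# Sample `n` noisy instances from prototypes with balanced class labels.
sample_split <- function(protos, spec, n) {
  labels <- rep_len(seq_along(protos), n)
  labels <- sample(labels)  # balanced within +/- 1, shuffled order
  samples <- lapply(labels, function(cl) {
    m <- protos[[cl]]
    flip <- matrix(stats::runif(length(m)) < spec$flip_prob,
                   nrow(m), ncol(m))
    m[flip] <- spec$fg_intensity - m[flip]  # fg -> 0, bg -> fg
    m
  })
  list(samples = samples, labels = labels)
}

#' Sample a full synthetic dataset
#'
#' Draws prototypes with [make_prototypes()] and then samples balanced,
#' shuffled train and test splits with independent per-pixel flip noise.
#' Fully reproducible from the spec.
#'
#' @param spec A [synthetic_spec()].
#'
#' @return A list of class `"vdsp_dataset"` with elements `train` and `test`
#'   (each a list with `samples`, a list of pixel matrices, and `labels`,
#'   integer class ids), `prototypes`, and `meta` (source and spec).
#' @export
sample_dataset <- function(spec) {
  protos <- make_prototypes(spec)  # also seeds the RNG
  train <- sample_split(protos, spec, spec$n_train)
  test <- sample_split(protos, spec, spec$n_test)
  structure(
    list(train = train, test = test, prototypes = protos,
         meta = list(source = "synthetic", spec = spec)),
    class = "vdsp_dataset"
  )
}

#' Read an IDX-format array file
#'
#' Parses the big-endian IDX container used by the classic handwritten-digit
#' distribution: magic `0x00000803` for 3-D uint8 image tensors
#' (count x rows x cols) and `0x00000801` for 1-D uint8 label vectors.
#'
#' @param path Path to an IDX file.
#'
#' @return For image files, a 3-D integer array `count x rows x cols`; for
#'   label files, an integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  if (!magic %in% c(0x00000801L, 0x00000803L)) {
    stop(sprintf("not an IDX uint8 file (magic 0x%08x)", magic), call. = FALSE)
  }
  n_dims <- if (magic == 0x00000803L) 3L else 1L
  dims <- readBin(con, "integer", n = n_dims, size = 4, endian = "big")
  n_items <- prod(dims)
  payload <- readBin(con, "integer", n = n_items, size = 1, signed = FALSE)
  if (length(payload) < n_items) {
    stop("truncated IDX payload", call. = FALSE)
  }
  if (n_dims == 1L) {
    payload
  } else {
    # IDX stores row-major: item, then row, then column fastest
    aperm(array(payload, dim = rev(dims)), c(3L, 2L, 1L))
  }
}

#' Write an array to IDX format
#'
#' Inverse of [read_idx()]; used for interchange and round-trip testing.
#'
#' @param x An integer vector (labels) or 3-D array (count x rows x cols)
#'   with values in `[0, 255]`.
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path) {
  if (any(x < 0 | x > 255)) stop("values must be in [0, 255]", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.array(x) && length(dim(x)) == 3L) {
    writeBin(0x00000803L, con, size = 4, endian = "big")
    writeBin(as.integer(dim(x)), con, size = 4, endian = "big")
    payload <- as.integer(aperm(x, c(3L, 2L, 1L)))
  } else {
    writeBin(0x00000801L, con, size = 4, endian = "big")
    writeBin(length(x), con, size = 4, endian = "big")
    payload <- as.integer(x)
  }
  writeBin(as.raw(payload), con)
  invisible(path)
}

#' Load a handwritten-digit style dataset from IDX files
#'
#' @param images_path,labels_path Paths to the image tensor and label vector
#'   files (uncompressed IDX).
#'
#' @return A list with `samples` (list of pixel matrices), `labels`
#'   (1-based integer class ids) and `meta`.
#' @export
read_idx_dataset <- function(images_path, labels_path) {
  imgs <- read_idx(images_path)
  labels <- read_idx(labels_path)
  if (dim(imgs)[1] != length(labels)) {
    stop("image and label counts differ", call. = FALSE)
  }
  samples <- lapply(seq_len(dim(imgs)[1]), function(i) imgs[i, , ])
  list(samples = samples, labels = as.integer(labels) + 1L,
       meta = list(source = "idx",
                   files = c(images_path, labels_path)))
}
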