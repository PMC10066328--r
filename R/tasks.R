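# Episode construction: synthetic task sources, IDX-format datasets, and the
# M-way K-shot episodic sampler.

#' Specification of a synthetic task source
#'
#' Describes a pool of image-like classes that emulates the statistical role
#' of a handwritten-character database: a fixed per-class prototype pattern
#' plus independent pixel noise, with values clipped to \[0, 1\]. Two
#' prototype structures are available: `"gaussian_prototypes"` (dense
#' prototypes, pixel values spread around mid-gray) and `"blob_glyphs"`
#' (sparse glyphs of bright blobs on a dark background, closer in spirit to
#' character strokes).
#'
#' Defaults mirror the 47-class, 784-pixel setting of the episodic
#' experiments and are calibrated so that a 5-way task is learnable well
#' above chance by plain online backprop with learning rate 1e-3 within 250
#' samples.
#'
#' @param class_pool_size number of classes in the pool (>= 20).
#' @param input_dim flattened input dimension (default 784).
#' @param prototype_scale spread of prototype pixel values (default 0.3).
#' @param noise_scale standard deviation of per-pixel sample noise
#'   (default 0.2).
#' @param structure `"gaussian_prototypes"` or `"blob_glyphs"`.
#' @return an object of class `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(class_pool_size = 47, input_dim = 784,
                                prototype_scale = 0.3, noise_scale = 0.2,
                                structure = c("gaussian_prototypes",
                                              "blob_glyphs")) {
  structure <- match.arg(structure)
  if (class_pool_size < 20) stop("class_pool_size must be >= 20")
  if (input_dim < 1) stop("input_dim must be positive")
  if (prototype_scale <= 0 || noise_scale < 0)
    stop("prototype_scale must be > 0 and noise_scale >= 0")
  base::structure(
    list(class_pool_size = as.integer(class_pool_size),
         input_dim = as.integer(input_dim),
         prototype_scale = prototype_scale, noise_scale = noise_scale,
         structure = structure),
    class = "synthetic_task_spec"
  )
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# one sparse glyph prototype: Gaussian bumps on a near-square pixel grid;
# blob count and width scale with the grid so small grids stay sparse
# (side 28 gives the default 6 blobs of width 1.6)
.glyph_prototype <- function(input_dim, n_blobs = NULL, width = NULL) {
  side <- ceiling(sqrt(input_dim))
  if (is.null(n_blobs)) n_blobs <- max(2, round(side / 5))
  if (is.null(width)) width <- max(1, side / 17.5)
  gx <- (seq_len(input_dim) - 1) %% side
  gy <- (seq_len(input_dim) - 1) %/% side
  proto <- numeric(input_dim)
  cx <- stats::runif(n_blobs, 0, side - 1)
  cy <- stats::runif(n_blobs, 0, side - 1)
  amp <- stats::runif(n_blobs, 0.7, 1)
  for (b in seq_len(n_blobs)) {
    proto <- proto + amp[b] * exp(-((gx - cx[b])^2 + (gy - cy[b])^2) /
                                    (2 * width^2))
  }
  .clip01(proto)
}

#' Build a synthetic task source
#'
#' Draws one prototype per class (deterministically from `seed`) and returns
#' a dataset handle with the same sampling interface as an IDX-backed
#' dataset. Individual samples are `prototype + noise_scale * N(0, 1)`
#' clipped to \[0, 1\]; with `noise_scale = 0` every sample equals its class
#' prototype.
#'
#' @param spec a [synthetic_task_spec()].
#' @param seed integer seed for the prototype draw.
#' @return an object of class `task_source`.
#' @export
make_synthetic_source <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  protos <- .with_seed(seed, {
    switch(spec$structure,
      gaussian_prototypes = vapply(seq_len(spec$class_pool_size), function(c)
        .clip01(0.5 + spec$prototype_scale * stats::rnorm(spec$input_dim)),
        numeric(spec$input_dim)),
      blob_glyphs = vapply(seq_len(spec$class_pool_size), function(c)
        .glyph_prototype(spec$input_dim), numeric(spec$input_dim))
    )
  })
  structure(list(type = "synthetic", spec = spec, seed = seed,
                 prototypes = protos,  # input_dim x n_classes
                 n_classes = spec$class_pool_size,
                 input_dim = spec$input_dim),
            class = "task_source")
}

# draw n samples of class c with the *current* RNG stream
.draw_synthetic <- function(source, class_id, n) {
  p <- source$prototypes[, class_id]
  noise <- matrix(stats::rnorm(n * length(p), sd = source$spec$noise_scale),
                  nrow = n, byrow = TRUE)
  .clip01(sweep(noise, 2, p, `+`))
}

#' Read an IDX-format file
#'
#' Reads the big-endian IDX container used by the MNIST family of datasets
#' (magic 2051 for uint8 image tensors, 2049 for label vectors).
#'
#' @param path file path.
#' @return for images, a numeric matrix (n x pixels) scaled to \[0, 1\]; for
#'   labels, an integer vector.
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (magic == 2051L) {
    dims <- readBin(con, "integer", 3, size = 4, endian = "big")
    raw <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
    matrix(raw / 255, nrow = dims[1], ncol = dims[2] * dims[3], byrow = TRUE)
  } else if (magic == 2049L) {
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    readBin(con, "integer", n, size = 1, signed = FALSE)
  } else {
    stop(sprintf("unsupported IDX magic number %d in %s", magic, path))
  }
}

#' Write an IDX-format file
#'
#' @param x for images, a numeric matrix (n x pixels) with values in
#'   \[0, 1\] (quantized to uint8) and an attribute-free square-ish layout;
#'   for labels, an integer vector.
#' @param path output path.
#' @param type `"images"` or `"labels"`.
#' @param rows,cols image dimensions; default a near-square factorization.
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, type = c("images", "labels"),
                      rows = NULL, cols = NULL) {
  type <- match.arg(type)
  con <- file(path, "wb")
  on.exit(close(con))
  if (type == "images") {
    if (is.null(rows)) {
      rows <- ceiling(sqrt(ncol(x)))
      cols <- ceiling(ncol(x) / rows)
    }
    if (rows * cols != ncol(x))
      stop("rows * cols must equal the pixel count")
    writeBin(as.integer(c(2051L, nrow(x), rows, cols)), con, size = 4,
             endian = "big")
    vals <- as.integer(round(t(x) * 255))
    writeBin(as.raw(pmin(pmax(vals, 0L), 255L)), con)
  } else {
    writeBin(as.integer(c(2049L, length(x))), con, size = 4, endian = "big")
    writeBin(as.raw(as.integer(x)), con)
  }
  invisible(path)
}

#' Load an IDX image/label pair as a task source
#'
#' @param image_path,label_path IDX files (uncompressed).
#' @return an object of class `task_source`. Class labels in the file may be
#'   any 0-based integers; they are mapped to 1..n_classes in file order.
#' @export
idx_source <- function(image_path, label_path) {
  images <- read_idx(image_path)
  labels <- read_idx(label_path)
  if (nrow(images) != length(labels))
    stop("image and label counts differ")
  classes <- sort(unique(labels))
  structure(list(type = "idx", images = images,
                 labels = match(labels, classes),
                 class_values = classes,
                 n_classes = length(classes),
                 input_dim = ncol(images)),
            class = "task_source")
}

#' Materialize a synthetic source as IDX files
#'
#' Writes `images.idx`, `labels.idx` and a `manifest.json` describing the
#' generator, so synthetic data can be consumed through the same on-disk
#' interface as a real dataset. Filenames carry no compression and the
#' manifest marks the data as synthetic.
#'
#' @param source a synthetic `task_source`.
#' @param out_dir output directory (created if needed).
#' @param n_per_class samples written per class (default 60 = K + Q).
#' @param seed seed for the sample noise.
#' @return named character vector of the files written, invisibly.
#' @export
materialize_source <- function(source, out_dir, n_per_class = 60, seed = 1) {
  stopifnot(identical(source$type, "synthetic"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_per_class * source$n_classes
  labels <- rep(seq_len(source$n_classes) - 1L, each = n_per_class)
  images <- .with_seed(seed, {
    do.call(rbind, lapply(seq_len(source$n_classes), function(c)
      .draw_synthetic(source, c, n_per_class)))
  })
  paths <- c(images = file.path(out_dir, "images.idx"),
             labels = file.path(out_dir, "labels.idx"),
             manifest = file.path(out_dir, "manifest.json"))
  write_idx(images, paths[["images"]], "images")
  write_idx(labels, paths[["labels"]], "labels")
  jsonlite::write_json(
    list(synthetic = TRUE, spec = unclass(source$spec),
         prototype_seed = source$seed, sample_seed = seed,
         n_per_class = n_per_class, n = n),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Sample one M-way episode
#'
#' Draws `M` classes without replacement from the source, then `K + Q`
#' items per class (without replacement for stored datasets; fresh noise
#' draws for synthetic sources), splits them into an online training stream
#' of length `M * K` and a query set of length `M * Q`, and shuffles the
#' training stream. Labels are relabeled to 1..M in the order the classes
#' were drawn; `class_ids` records the source classes.
#'
#' @param source a `task_source`.
#' @param M classes per task.
#' @param K training items per class.
#' @param Q query items per class.
#' @param seed integer seed; the episode is deterministic given the seed.
#' @return an object of class `episode_task` with fields `train_x`
#'   (`M*K` x input_dim), `train_y`, `query_x`, `query_y`, `class_ids`.
#' @export
sample_episode <- function(source, M, K, Q, seed) {
  stopifnot(inherits(source, "task_source"))
  if (M > source$n_classes)
    stop(sprintf("source has %d classes, cannot draw %d", source$n_classes, M))
  .with_seed(seed, {
    classes <- sample(source$n_classes, M)
    per_class <- lapply(classes, function(c) {
      if (source$type == "synthetic") {
        .draw_synthetic(source, c, K + Q)
      } else {
        idx <- which(source$labels == c)
        if (length(idx) < K + Q)
          stop(sprintf("class %d has %d items, need %d", c, length(idx), K + Q))
        source$images[sample(idx, K + Q), , drop = FALSE]
      }
    })
    train_x <- do.call(rbind, lapply(per_class, function(m) m[seq_len(K), , drop = FALSE]))
    query_x <- do.call(rbind, lapply(per_class, function(m) m[K + seq_len(Q), , drop = FALSE]))
    train_y <- rep(seq_len(M), each = K)
    query_y <- rep(seq_len(M), each = Q)
    ord <- sample(M * K)
    structure(list(train_x = train_x[ord, , drop = FALSE],
                   train_y = train_y[ord],
                   query_x = query_x, query_y = query_y,
                   class_ids = classes),
              class = "episode_task")
  })
}
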