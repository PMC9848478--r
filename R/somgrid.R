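#' Self-organizing map configuration
#'
#' Defaults follow the integration analysis configuration: a 10 x 10
#' grid with wrap-around ("circular"/toroidal) topology, 5000 online
#' training cycles, and a learning rate declining linearly from 0.09 to
#' 0.01. The neighborhood is a bubble (all nodes within the current
#' radius updated at full rate) whose initial radius defaults to the
#' 2/3 quantile of all node-to-node grid distances and shrinks linearly
#' to 0 over training.
#'
#' @param rows,cols grid dimensions (default 10 x 10 = 100 units).
#' @param toroidal wrap the grid edges (default `TRUE`).
#' @param rlen number of online training cycles (default 5000).
#' @param alpha_start,alpha_end learning-rate schedule endpoints.
#' @param neighbourhood `"bubble"` or `"gaussian"`.
#' @param radius initial neighborhood radius; `NULL` for the default.
#' @param seed RNG seed for initialization and presentation order.
#' @return List with class `som_config`.
#' @export
som_config <- function(rows = 10L, cols = 10L, toroidal = TRUE, rlen = 5000L,
                       alpha_start = 0.09, alpha_end = 0.01,
                       neighbourhood = c("bubble", "gaussian"),
                       radius = NULL, seed = 1L) {
  neighbourhood <- match.arg(neighbourhood)
  if (rows * cols < 2) stop("grid must have at least 2 units")
  if (rlen < 1) stop("rlen must be >= 1")
  if (!(alpha_start > alpha_end && alpha_end > 0))
    stop("need alpha_start > alpha_end > 0")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 toroidal = toroidal, rlen = as.integer(rlen),
                 alpha_start = alpha_start, alpha_end = alpha_end,
                 neighbourhood = neighbourhood, radius = radius,
                 seed = as.integer(seed)),
            class = "som_config")
}

#' Grid distances between SOM units
#'
#' Euclidean distance between unit positions on the grid; on a toroidal
#' grid each axis difference wraps, so opposite corners are neighbors.
#'
#' @param rows,cols grid dimensions.
#' @param toroidal wrap-around topology.
#' @return node x node distance matrix (row-major node order).
#' @export
som_grid_distances <- function(rows, cols, toroidal = TRUE) {
  coord <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  dr <- abs(outer(coord$row, coord$row, "-"))
  dc <- abs(outer(coord$col, coord$col, "-"))
  if (toroidal) {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  sqrt(dr^2 + dc^2)
}

#' Prepare a multi-assay feature matrix for SOM training
#'
#' Signal-like datasets (ChIP, ATAC, expression) are `log2(x+1)`
#' transformed and z-scaled per feature; methylation (already a bounded
#' fraction) is z-scaled without the log transform. Regions with
#' undefined methylation are dropped (and counted in a message), as are
#' constant features (sd 0, with a warning). Transform and scaling
#' records are kept so node summaries can report original-scale means.
#'
#' @param datasets named list of region x feature matrices (or named
#'   vectors) sharing rownames/names; values >= 0.
#' @param meth optional [region_methylation()] table or named numeric
#'   vector of methylated fractions.
#' @return A `feature_matrix`: list with `x` (scaled matrix),
#'   `transform`, `center`, `scale`.
#' @export
prepare_features <- function(datasets, meth = NULL) {
  as_mat <- function(d, nm) {
    if (is.null(dim(d))) d <- matrix(d, ncol = 1,
                                     dimnames = list(names(d), nm))
    as.matrix(d)
  }
  mats <- mapply(as_mat, datasets, names(datasets), SIMPLIFY = FALSE)
  ids <- rownames(mats[[1]])
  if (is.null(ids)) stop("datasets must carry region ids as rownames/names")
  for (m in mats)
    if (!identical(rownames(m), ids)) stop("datasets disagree on region index")
  x <- do.call(cbind, lapply(seq_along(mats), function(i) {
    m <- log2(mats[[i]] + 1)
    colnames(m) <- paste(names(mats)[i],
                         colnames(mats[[i]]) %||% seq_len(ncol(m)), sep = ".")
    m
  }))
  transform <- rep("log2p1", ncol(x))
  if (!is.null(meth)) {
    if (is.data.frame(meth)) {
      mm <- stats::setNames(ifelse(meth$defined, meth$mean_meth, NA_real_),
                            meth$region_id)
    } else mm <- meth
    x <- cbind(x, meth = mm[ids])
    transform <- c(transform, "identity")
  }
  drop_rows <- !complete.cases(x)
  if (any(drop_rows)) {
    message(sprintf("prepare_features: dropped %d region(s) with undefined values",
                    sum(drop_rows)))
    x <- x[!drop_rows, , drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- scl > 0
  if (any(!keep))
    warning("dropping constant feature(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  x <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  structure(list(x = x, transform = transform[keep],
                 center = ctr[keep], scale = scl[keep]),
            class = "feature_matrix")
}

#' Train a self-organizing map
#'
#' Classical online SOM: at each cycle one data row is presented, its
#' best-matching unit (BMU) is found by Euclidean distance, and the
#' codebook vectors within the current neighborhood radius are pulled
#' toward the sample by the current learning rate. Rate and radius both
#' decline linearly over `rlen` cycles (radius to 0, so training ends in
#' plain online k-means refinement). Fully deterministic for a fixed
#' config seed.
#'
#' @param features a [prepare_features()] result or a plain numeric
#'   matrix (rows = regions).
#' @param config a [som_config()].
#' @return A `som_fit`: list with `codebook` (node x feature),
#'   `assignment` (named node index per region), `qe` (quantization
#'   error trajectory), `grid_dist`, `config`, `features`.
#' @export
train_som <- function(features, config = som_config()) {
  fm <- if (inherits(features, "feature_matrix")) features else NULL
  x <- if (is.null(fm)) as.matrix(features) else fm$x
  if (!nrow(x)) stop("no rows to train on")
  m <- config$rows * config$cols
  if (nrow(x) < m)
    warning("fewer data rows than map units; map will be sparse")
  gd <- som_grid_distances(config$rows, config$cols, config$toroidal)
  r0 <- config$radius %||% unname(stats::quantile(gd[upper.tri(gd)], 2 / 3))
  rlen <- config$rlen

  codebook <- with_seed(config$seed, {
    # classical random init: uniform within each feature's data range;
    # starts far from the data so quantization error decreases through
    # the wide-radius ordering phase instead of being degraded by it
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    init <- matrix(runif(m * ncol(x)), m, ncol(x))
    init <- sweep(sweep(init, 2, hi - lo, "*"), 2, lo, "+")
    colnames(init) <- colnames(x)
    pres <- sample.int(nrow(x), rlen, replace = TRUE)
    qe_at <- unique(c(1L, seq(0L, rlen, by = max(1L, rlen %/% 10L))[-1], rlen))
    qe <- data.frame(cycle = integer(), qe = numeric())
    mean_qe <- function(cb) {
      d2 <- outer(rowSums(x^2), rowSums(cb^2), "+") - 2 * x %*% t(cb)
      mean(sqrt(pmax(apply(d2, 1, min), 0)))
    }
    qe <- rbind(qe, data.frame(cycle = 0L, qe = mean_qe(init)))
    cb <- init
    for (t in seq_len(rlen)) {
      v <- x[pres[t], ]
      d2 <- rowSums(sweep(cb, 2, v)^2)
      bmu <- which.min(d2)
      frac <- if (rlen > 1) (t - 1) / (rlen - 1) else 0
      alpha <- config$alpha_start +
        (config$alpha_end - config$alpha_start) * frac
      radius <- r0 * (1 - frac)
      if (config$neighbourhood == "bubble") {
        idx <- which(gd[bmu, ] <= radius)
        cb[idx, ] <- cb[idx, ] +
          alpha * sweep(-cb[idx, , drop = FALSE], 2, v, "+")
      } else {
        sig <- max(radius, 1e-8)
        w <- exp(-gd[bmu, ]^2 / (2 * sig^2))
        cb <- cb + (alpha * w) * sweep(-cb, 2, v, "+")
      }
      if (t %in% qe_at) qe <- rbind(qe, data.frame(cycle = t, qe = mean_qe(cb)))
    }
    attr(cb, "qe") <- qe
    cb
  })
  qe <- attr(codebook, "qe"); attr(codebook, "qe") <- NULL
  d2 <- outer(rowSums(x^2), rowSums(codebook^2), "+") - 2 * x %*% t(codebook)
  assignment <- stats::setNames(apply(d2, 1, which.min), rownames(x))
  structure(list(codebook = codebook, assignment = assignment, qe = qe,
                 grid_dist = gd, config = config, features = fm,
                 data = x),
            class = "som_fit")
}

#' @export
print.som_fit <- function(x, ...) {
  cat(sprintf("som_fit: %d x %d %sgrid, %d regions, final QE %.4f\n",
              x$config$rows, x$config$cols,
              if (x$config$toroidal) "toroidal " else "", length(x$assignment),
              x$qe$qe[nrow(x$qe)]))
  invisible(x)
}

#' Per-node summaries of a trained SOM
#'
#' Tabulates region labels per map unit and reports the mean feature
#' values of each unit's members on the original (pre-transform,
#' pre-scaling) scale when the fit was trained on a
#' [prepare_features()] matrix. Counts over all nodes sum to the number
#' of assigned regions; empty nodes have zero counts and `NaN` means.
#'
#' @param fit a [train_som()] result.
#' @param annotations optional named character vector: label per region.
#' @return List with `counts` (node x label), `n` (regions per node),
#'   `means` (node x feature).
#' @export
node_summary <- function(fit, annotations = NULL) {
  m <- nrow(fit$codebook)
  nodes <- factor(fit$assignment, levels = seq_len(m))
  n <- as.integer(table(nodes))
  x <- fit$data
  if (!is.null(fit$features)) {
    fm <- fit$features
    x <- sweep(sweep(x, 2, fm$scale, "*"), 2, fm$center, "+")
    for (j in seq_len(ncol(x)))
      if (fm$transform[j] == "log2p1") x[, j] <- 2^x[, j] - 1
  }
  means <- apply(x, 2, function(col) tapply(col, nodes, mean))
  counts <- NULL
  if (!is.null(annotations)) {
    lab <- annotations[names(fit$assignment)]
    counts <- table(node = nodes, label = lab)
  }
  list(counts = counts, n = n, means = means)
}
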