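# Correlation analysis, PCA catalyst map, diversity-based screening-set
# selection, and overlay of experimental outcomes on the map.

#' Assemble a descriptor matrix from records
#'
#' Row order follows the input order; column order is the canonical
#' [descriptor_names()] order.
#'
#' @param records List of [compute_descriptor_record()] results.
#' @return Numeric n x 14 matrix, rownames = catalyst ids.
#' @export
assemble_matrix <- function(records) {
  if (length(records) < 2L) stop("validation error: need at least 2 records")
  nm <- descriptor_names()
  ids <- vapply(records, function(r) r$catalyst_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate catalyst_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- matrix(NA_real_, length(records), length(nm),
              dimnames = list(ids, nm))
  for (i in seq_along(records)) {
    v <- records[[i]]$values
    missing <- setdiff(nm, names(v)[is.finite(v)])
    if (length(missing)) {
      stop(sprintf("validation error: catalyst '%s' is missing descriptor(s): %s",
                   ids[i], paste(missing, collapse = ", ")))
    }
    m[i, ] <- v[nm]
  }
  m
}

#' Standardize a descriptor matrix
#'
#' Column-wise z-scoring: each descriptor gets mean 0 and sample standard
#' deviation 1 (n - 1 denominator).
#'
#' @param m Numeric matrix with descriptor columns.
#' @return List with `values` (standardized matrix), `means`, `scales`.
#' @export
standardize_matrix <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("descriptor matrix must be numeric")
  means <- colMeans(m)
  scales <- apply(m, 2L, stats::sd)
  bad <- which(!is.finite(scales) | scales < .Machine$double.eps^0.5)
  if (length(bad)) {
    stop("validation error: constant (zero-variance) descriptor column: ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  z <- sweep(sweep(m, 2L, means, "-"), 2L, scales, "/")
  list(values = z, means = means, scales = scales)
}

#' Pearson correlation matrix of descriptors
#'
#' @param m Numeric n x p matrix (n >= 3) of descriptor values.
#' @return p x p symmetric matrix of Pearson R with unit diagonal.
#' @export
correlation_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("validation error: need at least 3 rows for correlation")
  sds <- apply(m, 2L, stats::sd)
  bad <- which(!is.finite(sds) | sds < .Machine$double.eps^0.5)
  if (length(bad)) {
    stop("validation error: zero-variance column: ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  stats::cor(m)
}

#' Fit a PCA catalyst map
#'
#' Standardizes the descriptor matrix (z-score per column, n - 1
#' denominators) and computes the principal components of the resulting
#' correlation structure via [stats::prcomp()]. Loading signs are fixed so
#' that each column's largest-magnitude entry is positive; scores are the
#' standardized data projected on the loadings. Explained-variance fractions
#' are eigenvalue fractions over all p components, so they sum to 1 when
#' `n_components = p`.
#'
#' @param m Numeric n x p descriptor matrix (rownames = catalyst ids).
#' @param n_components Number of components to retain, 1..p.
#' @param standardize If `FALSE`, the matrix is only centred, not scaled
#'   (for data already on a common scale).
#' @return An object of class `pca_model`: `means`, `scales`, `loadings`
#'   (p x m), `scores` (n x m), `explained_variance` (length m fractions),
#'   `eigenvalues` (all p), `mse_loss`, `n_components`.
#' @export
pca_fit <- function(m, n_components = 3L, standardize = TRUE) {
  m <- as.matrix(m)
  p <- ncol(m)
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > p) {
    stop(sprintf("validation error: n_components must be in 1..%d", p))
  }
  if (nrow(m) < 2L) stop("validation error: need at least 2 rows")
  if (standardize) {
    st <- standardize_matrix(m)
    z <- st$values; means <- st$means; scales <- st$scales
  } else {
    means <- colMeans(m)
    scales <- stats::setNames(rep(1, p), colnames(m))
    z <- sweep(m, 2L, means, "-")
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  eig <- pc$sdev^2
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # deterministic sign convention: largest-|entry| of each column positive
  for (j in seq_len(ncol(load))) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) load[, j] <- -load[, j]
  }
  scores <- z %*% load
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(n_components))
  recon <- scores %*% t(load)
  model <- structure(list(means = means, scales = scales,
                          loadings = load, scores = scores,
                          explained_variance = eig[seq_len(n_components)] / sum(eig),
                          eigenvalues = eig,
                          mse_loss = mean((z - recon)^2),
                          n_components = n_components,
                          standardized = standardize),
                     class = "pca_model")
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d descriptors, %d catalysts\n",
              x$n_components, nrow(x$loadings), nrow(x$scores)))
  cat(sprintf("explained variance: %s (cumulative %.1f%%); projection MSE %.4f\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
              100 * sum(x$explained_variance), x$mse_loss))
  invisible(x)
}

# standardize new data with a fitted model's constants
.model_transform <- function(model, m) {
  m <- as.matrix(m)
  if (ncol(m) != length(model$means)) {
    stop("validation error: column count does not match the fitted model")
  }
  sweep(sweep(m, 2L, model$means, "-"), 2L, model$scales, "/")
}

#' Mean squared projection loss
#'
#' Mean over all n x p entries of the squared difference between the
#' standardized matrix and its rank-m reconstruction from the model's
#' loadings. Unit-free because it is evaluated on the standardized scale.
#'
#' @param model A [pca_fit()] model.
#' @param m The descriptor matrix the model was fitted on (raw scale).
#' @return Non-negative scalar loss.
#' @export
projection_mse <- function(model, m) {
  stopifnot(inherits(model, "pca_model"))
  z <- .model_transform(model, m)
  recon <- (z %*% model$loadings) %*% t(model$loadings)
  mean((z - recon)^2)
}

#' Greedy maximin screening-set selection
#'
#' Diversity-based selection in PCA score space: start from the catalyst
#' farthest from the score centroid, then iteratively add the catalyst that
#' maximizes the minimum Euclidean distance to the already-chosen set. Ties
#' are broken by input (row) order.
#'
#' @param model A [pca_fit()] model.
#' @param k Number of catalysts to select, 1..n.
#' @param n_dims Number of leading score dimensions to use (default: all
#'   retained components).
#' @return Character vector of k catalyst ids (or row indices as character
#'   when the score matrix has no rownames).
#' @export
select_screening_set <- function(model, k, n_dims = NULL) {
  stopifnot(inherits(model, "pca_model"))
  s <- model$scores
  n <- nrow(s)
  if (is.null(n_dims)) n_dims <- ncol(s)
  if (n_dims < 1L || n_dims > ncol(s)) {
    stop("validation error: n_dims out of range")
  }
  if (k < 1L || k > n) stop(sprintf("validation error: k must be in 1..%d", n))
  x <- s[, seq_len(n_dims), drop = FALSE]
  ids <- rownames(s)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  centroid <- colMeans(x)
  d0 <- sqrt(rowSums(sweep(x, 2L, centroid, "-")^2))
  chosen <- which.max(d0)  # which.max takes the first (lowest index) on ties
  mind <- sqrt(rowSums(sweep(x, 2L, x[chosen, ], "-")^2))
  while (length(chosen) < k) {
    mind[chosen] <- -Inf
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    dn <- sqrt(rowSums(sweep(x, 2L, x[nxt, ], "-")^2))
    mind <- pmin(mind, dn)
  }
  ids[chosen]
}

#' Read an outcomes table
#'
#' CSV with columns `catalyst_id`, `solvent`, `yield_pct` and optional
#' `ratio_6_7` (product ratio, positive) and `conversion` (percent).
#'
#' @param path CSV path.
#' @return data.frame of validated outcome records.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("catalyst_id", "solvent", "yield_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("outcomes CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(df$yield_pct) | df$yield_pct < 0 | df$yield_pct > 100)) {
    stop("validation error: yield_pct must lie in [0, 100]")
  }
  if (!is.null(df$ratio_6_7) &&
      any(is.finite(df$ratio_6_7) & df$ratio_6_7 <= 0)) {
    stop("validation error: ratio_6_7 must be positive when present")
  }
  df
}

#' Overlay experimental outcomes on the catalyst map
#'
#' Joins outcome records to PCA scores and renders the map: screened
#' catalysts as circles with area proportional to yield (or conversion) and
#' a diverging colour for the log product ratio; unscreened catalysts as
#' grey background points. Multiple solvents per catalyst are allowed (one
#' marker each).
#'
#' @param model A [pca_fit()] model whose scores carry catalyst rownames.
#' @param outcomes data.frame as returned by [read_outcomes()].
#' @param axes Integer pair of principal components to plot (default 1:2).
#' @param file Optional PNG path; when `NULL` nothing is drawn.
#' @param size_by Column driving marker size: `"yield_pct"` or `"conversion"`.
#' @return Invisibly, the joined table: one row per outcome plus one
#'   background row per unscreened catalyst (`screened` flag).
#' @export
overlay_outcomes <- function(model, outcomes, axes = c(1L, 2L), file = NULL,
                             size_by = "yield_pct") {
  stopifnot(inherits(model, "pca_model"))
  s <- model$scores
  ids <- rownames(s)
  if (is.null(ids)) stop("model scores carry no catalyst ids")
  if (length(axes) != 2L || any(axes < 1L) || any(axes > ncol(s))) {
    stop("validation error: axes must name two retained components")
  }
  unknown <- setdiff(unique(outcomes$catalyst_id), ids)
  if (length(unknown)) {
    stop("validation error: outcome catalyst_id(s) not on the map: ",
         paste(unknown, collapse = ", "))
  }
  if (!size_by %in% names(outcomes)) {
    stop("validation error: size_by column absent from outcomes: ", size_by)
  }
  oi <- match(outcomes$catalyst_id, ids)
  joined <- data.frame(catalyst_id = outcomes$catalyst_id,
                       solvent = outcomes$solvent,
                       x = s[oi, axes[1L]], y = s[oi, axes[2L]],
                       yield_pct = outcomes$yield_pct,
                       ratio_6_7 = if (is.null(outcomes$ratio_6_7)) NA_real_
                                   else outcomes$ratio_6_7,
                       conversion = if (is.null(outcomes$conversion)) NA_real_
                                    else outcomes$conversion,
                       screened = TRUE,
                       stringsAsFactors = FALSE)
  bg_ids <- setdiff(ids, outcomes$catalyst_id)
  if (length(bg_ids)) {
    bi <- match(bg_ids, ids)
    joined <- rbind(joined,
                    data.frame(catalyst_id = bg_ids, solvent = NA_character_,
                               x = s[bi, axes[1L]], y = s[bi, axes[2L]],
                               yield_pct = NA_real_, ratio_6_7 = NA_real_,
                               conversion = NA_real_, screened = FALSE,
                               stringsAsFactors = FALSE))
  }
  rownames(joined) <- NULL
  if (!is.null(file)) {
    .render_overlay(joined, axes, file, size_by)
  }
  invisible(joined)
}

# deterministic rendering: documented size/colour mappings, no defaults left
# to the device
.render_overlay <- function(joined, axes, file, size_by) {
  grDevices::png(file, width = 1200L, height = 1000L, res = 150L)
  on.exit(grDevices::dev.off())
  sc <- joined[joined$screened, , drop = FALSE]
  bg <- joined[!joined$screened, , drop = FALSE]
  sz <- sc[[size_by]]
  sz[!is.finite(sz)] <- 0
  # marker radius: 0.6 + 2.4 * sqrt(fraction); zero outcome keeps minimum size
  cex <- 0.6 + 2.4 * sqrt(pmax(sz, 0) / 100)
  col <- rep("#2e7d32", nrow(sc))  # single hue when no ratio is given
  if (any(is.finite(sc$ratio_6_7))) {
    lr <- log10(sc$ratio_6_7)
    lim <- max(abs(lr[is.finite(lr)]), 1e-6)
    ramp <- grDevices::colorRamp(c("#1a4f9c", "#f2f2f2", "#b2182b"))
    col <- vapply(lr, function(v) {
      if (!is.finite(v)) return("#bdbdbd")
      rgb <- ramp((v + lim) / (2 * lim))
      grDevices::rgb(rgb[1L], rgb[2L], rgb[3L], maxColorValue = 255)
    }, character(1L))
  }
  xl <- paste0("PC", axes[1L]); yl <- paste0("PC", axes[2L])
  graphics::plot(joined$x, joined$y, type = "n", xlab = xl, ylab = yl,
                 main = sprintf("Catalyst map (%s vs %s)", xl, yl))
  graphics::abline(h = 0, v = 0, col = "#dddddd")
  if (nrow(bg)) {
    graphics::points(bg$x, bg$y, pch = 19, cex = 0.7, col = "#aaaaaa")
    graphics::text(bg$x, bg$y, bg$catalyst_id, pos = 3, cex = 0.5,
                   col = "#888888")
  }
  if (nrow(sc)) {
    graphics::points(sc$x, sc$y, pch = 21, cex = cex, bg = col,
                     col = "#333333")
    graphics::text(sc$x, sc$y, sc$catalyst_id, pos = 1, cex = 0.55)
  }
  invisible(NULL)
}

#' Write a descriptor matrix as CSV
#'
#' One row per catalyst: `catalyst_id` column followed by the 14 descriptor
#' columns. The round-trip with [read_descriptor_csv()] is exact to the
#' printed precision (15 significant digits).
#'
#' @param m Descriptor matrix (rownames = catalyst ids).
#' @param path Output CSV path.
#' @param metadata Optional named list written as `# key: value` header
#'   comment lines (parameter provenance).
#' @return Invisibly, `path`.
#' @export
write_descriptor_csv <- function(m, path, metadata = NULL) {
  df <- data.frame(catalyst_id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, function(v) paste(format(v), collapse = " "),
                              character(1L))), con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.15g", m[i, ])), collapse = ",")
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read a descriptor CSV
#'
#' @param path CSV path written by [write_descriptor_csv()] (or a transcribed
#'   external descriptor table with a `catalyst_id` column and numeric
#'   descriptor columns; `# comment` header lines are ignored).
#' @return Numeric matrix with catalyst-id rownames.
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!"catalyst_id" %in% names(df)) {
    stop("descriptor CSV must have a catalyst_id column")
  }
  ids <- as.character(df$catalyst_id)
  m <- as.matrix(df[setdiff(names(df), "catalyst_id")])
  if (!is.numeric(m)) stop("descriptor columns must be numeric")
  if (anyNA(m)) stop("validation error: missing descriptor values in ", path)
  rownames(m) <- ids
  m
}

#' Serialize a PCA model to a structured text document
#'
#' @param model A [pca_fit()] model.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  doc <- list(n_components = model$n_components,
              standardized = model$standardized,
              descriptor_names = names(model$means),
              means = as.numeric(model$means),
              scales = as.numeric(model$scales),
              eigenvalues = as.numeric(model$eigenvalues),
              explained_variance = as.numeric(model$explained_variance),
              mse_loss = model$mse_loss,
              loadings = lapply(seq_len(ncol(model$loadings)),
                                function(j) as.numeric(model$loadings[, j])),
              catalyst_ids = rownames(model$scores),
              scores = lapply(seq_len(ncol(model$scores)),
                              function(j) as.numeric(model$scores[, j])))
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read a PCA model document
#'
#' @param path YAML path written by [write_pca_model()].
#' @return A `pca_model`.
#' @export
read_pca_model <- function(path) {
  doc <- yaml::read_yaml(path)
  p <- length(doc$means)
  m <- doc$n_components
  load <- do.call(cbind, lapply(doc$loadings, as.numeric))
  scores <- do.call(cbind, lapply(doc$scores, as.numeric))
  dimnames(load) <- list(doc$descriptor_names, paste0("PC", seq_len(m)))
  dimnames(scores) <- list(doc$catalyst_ids, paste0("PC", seq_len(m)))
  structure(list(means = stats::setNames(as.numeric(doc$means), doc$descriptor_names),
                 scales = stats::setNames(as.numeric(doc$scales), doc$descriptor_names),
                 loadings = load, scores = scores,
                 explained_variance = as.numeric(doc$explained_variance),
                 eigenvalues = as.numeric(doc$eigenvalues),
                 mse_loss = as.numeric(doc$mse_loss),
                 n_components = as.integer(m),
                 standardized = isTRUE(doc$standardized)),
            class = "pca_model")
}

#' Render a correlation heatmap
#'
#' Deterministic image of a Pearson correlation matrix: blue-white-red ramp
#' over [-1, 1], descriptors in canonical order, coefficients printed in
#' each cell.
#'
#' @param r Correlation matrix from [correlation_matrix()].
#' @param file PNG output path.
#' @return Invisibly, `file`.
#' @export
plot_correlation_heatmap <- function(r, file) {
  p <- ncol(r)
  grDevices::png(file, width = 1200L, height = 1100L, res = 140L)
  on.exit(grDevices::dev.off())
  pal <- grDevices::colorRampPalette(c("#1a4f9c", "#f7f7f7", "#b2182b"))(201L)
  graphics::par(mar = c(7, 7, 2, 1))
  graphics::image(seq_len(p), seq_len(p), t(r[p:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Pearson R correlation map")
  graphics::axis(1L, at = seq_len(p), labels = colnames(r), las = 2L,
                 cex.axis = 0.7)
  graphics::axis(2L, at = seq_len(p), labels = rev(rownames(r)), las = 2L,
                 cex.axis = 0.7)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    graphics::text(j, p - i + 1L, sprintf("%.2f", r[i, j]), cex = 0.45)
  }
  invisible(file)
}

#' Render a PCA score/loading map
#'
#' Scores as labelled points with loading vectors overlaid (scaled to the
#' score range), for one pair of principal components.
#'
#' @param model A [pca_fit()] model.
#' @param axes Integer pair of components.
#' @param file PNG output path.
#' @return Invisibly, `file`.
#' @export
plot_pca_map <- function(model, axes = c(1L, 2L), file) {
  stopifnot(inherits(model, "pca_model"))
  s <- model$scores[, axes, drop = FALSE]
  l <- model$loadings[, axes, drop = FALSE]
  scale_arrow <- 0.8 * max(abs(s)) / max(abs(l))
  grDevices::png(file, width = 1200L, height = 1000L, res = 150L)
  on.exit(grDevices::dev.off())
  ev <- 100 * model$explained_variance[axes]
  graphics::plot(s[, 1L], s[, 2L], pch = 19, col = "#2b6cb0",
                 xlab = sprintf("PC%d (%.1f%%)", axes[1L], ev[1L]),
                 ylab = sprintf("PC%d (%.1f%%)", axes[2L], ev[2L]),
                 main = "PCA catalyst map")
  graphics::abline(h = 0, v = 0, col = "#dddddd")
  graphics::text(s[, 1L], s[, 2L], rownames(s), pos = 3, cex = 0.55)
  graphics::arrows(0, 0, l[, 1L] * scale_arrow, l[, 2L] * scale_arrow,
                   length = 0.08, col = "#c05621")
  graphics::text(l[, 1L] * scale_arrow, l[, 2L] * scale_arrow,
                 rownames(l), cex = 0.55, col = "#c05621", pos = 4)
  invisible(file)
}
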