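#' Circular count fingerprints from chemical structures
#'
#' Computes hashed circular (Morgan-style) substructure count fingerprints:
#' every atom contributes one environment identifier per radius from 0 up to
#' `radius` (atoms without heavy-atom neighbours only contribute the radius-0
#' environment), identifiers are hashed and folded onto `bit_length` columns,
#' and fold collisions accumulate as counts. Structure parsing is delegated to
#' \pkg{ChemmineR}/\pkg{ChemmineOB}; this function owns only the environment
#' enumeration, hashing and folding.
#'
#' @param smiles character vector of SMILES (named or not), or `NULL`.
#' @param sdf a `ChemmineR::SDFset`, or path to an SDF file, or `NULL`.
#' @param bit_length fingerprint length (default 256).
#' @param radius maximum environment radius (default 2).
#' @return Integer count matrix, one row per parsable structure (rownames =
#'   input names or `cmpd<i>`), `bit_length` columns. Unparsable structures
#'   are dropped with a warning; if none parse, an error is raised.
#' @export
fingerprints_from_structures <- function(smiles = NULL, sdf = NULL,
                                         bit_length = 256L, radius = 2L) {
  bit_length <- check_count(bit_length, "bit_length", min = 8L)
  radius <- check_count(radius, "radius", min = 0L)
  if (is.null(smiles) == is.null(sdf)) stopf("supply exactly one of 'smiles' or 'sdf'")
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stopf("structure parsing requires the 'ChemmineR' package")
  }
  mols <- if (!is.null(smiles)) {
    nm <- if (is.null(names(smiles))) sprintf("cmpd%d", seq_along(smiles)) else names(smiles)
    lapply(seq_along(smiles), function(i) parse_smiles_one(smiles[[i]], nm[i]))
  } else {
    sdfset <- if (is.character(sdf)) ChemmineR::read.SDFset(sdf) else sdf
    nm <- ChemmineR::sdfid(sdfset)
    lapply(seq_along(sdfset), function(i) mol_graph_from_sdf(sdfset[[i]], nm[i]))
  }
  ok <- !vapply(mols, is.null, TRUE)
  if (!any(ok)) stopf("no structure could be parsed")
  if (any(!ok)) {
    warning(sprintf("skipped %d unparsable structure(s)", sum(!ok)), call. = FALSE)
  }
  mols <- mols[ok]
  fp <- t(vapply(mols, function(g) circular_counts(g, bit_length, radius),
                 integer(bit_length)))
  rownames(fp) <- vapply(mols, function(g) g$name, "")
  colnames(fp) <- sprintf("bit%03d", seq_len(bit_length))
  fp
}

# Parse one SMILES via ChemmineOB; returns NULL on failure. The raw SDF text
# is kept because ChemmineR's reader returns an empty atom block for
# single-heavy-atom molecules.
parse_smiles_one <- function(smi, name) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stopf("SMILES parsing requires the 'ChemmineOB' package")
  }
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smi, " ", name, "\n")),
    error = function(e) NULL)
  if (is.null(txt) || !nzchar(txt)) return(NULL)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  sdfobj <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(lines))[[1]],
    error = function(e) NULL)
  mol_graph_from_sdf(sdfobj, name, raw_lines = lines)
}

# Extract (element symbols, bond list) from a ChemmineR SDF object, falling
# back to the raw V2000 atom lines for records ChemmineR mis-parses.
mol_graph_from_sdf <- function(sdfobj, name, raw_lines = NULL) {
  ab <- if (!is.null(sdfobj)) {
    tryCatch(ChemmineR::atomblock(sdfobj), error = function(e) NULL)
  }
  bb <- if (!is.null(sdfobj)) {
    tryCatch(ChemmineR::bondblock(sdfobj), error = function(e) NULL)
  }
  elems <- if (!is.null(ab) && nrow(ab) > 0 && !is.null(rownames(ab)) &&
               all(grepl("_", rownames(ab)))) {
    sub("_.*", "", rownames(ab))
  } else {
    if (is.null(raw_lines)) {
      raw_lines <- tryCatch(ChemmineR::sdf2str(sdfobj), error = function(e) NULL)
    }
    v2000_atoms(raw_lines)
  }
  if (is.null(elems) || length(elems) == 0) return(NULL)
  bonds <- if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3 &&
               any(bb[, 1] > 0)) {
    cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
          order = as.integer(bb[, 3]))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
  }
  list(name = name, elements = elems, bonds = bonds)
}

# Atom symbols straight from a V2000 molfile block (counts line is line 4).
v2000_atoms <- function(lines) {
  if (is.null(lines) || length(lines) < 4) return(NULL)
  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  if (is.na(n_atoms) || n_atoms < 1) return(NULL)
  if (length(lines) < 4 + n_atoms) return(NULL)
  trimws(substr(lines[5:(4 + n_atoms)], 32, 34))
}

# Deterministic 31-bit string hash (polynomial rolling).
str_hash31 <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  h
}

# Enumerate circular environments and fold to counts.
circular_counts <- function(g, bit_length, radius) {
  n <- length(g$elements)
  counts <- integer(bit_length)
  # heavy-atom adjacency with bond orders
  nbrs <- vector("list", n)
  if (nrow(g$bonds) > 0) {
    for (b in seq_len(nrow(g$bonds))) {
      i <- g$bonds[b, 1]; j <- g$bonds[b, 2]; o <- g$bonds[b, 3]
      nbrs[[i]] <- rbind(nbrs[[i]], c(j, o))
      nbrs[[j]] <- rbind(nbrs[[j]], c(i, o))
    }
  }
  deg <- vapply(nbrs, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  # radius-0 invariant: element + heavy degree
  ids <- vapply(seq_len(n), function(i)
    str_hash31(paste0(g$elements[i], ":", deg[i])), numeric(1))
  add <- function(id) {
    bit <- (id %% bit_length) + 1L
    counts[bit] <<- counts[bit] + 1L
  }
  for (i in seq_len(n)) add(ids[i])
  if (radius >= 1) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (i in seq_len(n)) {
        if (deg[i] == 0L) next  # isolated atoms stop at radius 0
        nb <- nbrs[[i]]
        parts <- paste0(nb[, 2], "|", ids[nb[, 1]])
        new_ids[i] <- str_hash31(paste0(r, "#", ids[i], "#",
                                        paste(sort(parts), collapse = ",")))
        add(new_ids[i])
      }
      ids <- new_ids
    }
  }
  counts
}

#' Train a periodic (toroidal) self-organizing map on fingerprints
#'
#' Online SOM on a `width` x `height` toroidal grid. Neuron weights are
#' initialized from a uniform distribution spanning the per-column ranges of
#' the input vectors. At each step the best-matching unit (BMU) and its
#' Gaussian neighbourhood move toward the presented input; the neighbourhood
#' radius decays linearly from `max(width, height)/2` to 1 and the learning
#' rate from 0.5 to 0.01 over the run. Presentation order is reshuffled each
#' epoch under the seed, so results are deterministic.
#'
#' @param fp compound x bit count matrix (rownames = compound ids).
#' @param width,height map dimensions (default 50 x 50).
#' @param epochs passes over the compound set.
#' @param seed integer seed.
#' @param alpha length-2 learning-rate schedule (start, end).
#' @param radius0 starting neighbourhood radius; default `max(width, height)/2`.
#' @return An object of class `som_grid`: list with `weights` ((width*height)
#'   x bits, neuron k = column-major cell (row r, col c) with
#'   k = (c-1)*height + r), `width`, `height`, `periodic = TRUE`.
#' @export
train_som <- function(fp, width = 50L, height = 50L, epochs = 10L, seed = 1L,
                      alpha = c(0.5, 0.01), radius0 = NULL) {
  width <- check_count(width, "width", min = 2L)
  height <- check_count(height, "height", min = 2L)
  epochs <- check_count(epochs, "epochs")
  if (!is.matrix(fp) || nrow(fp) < 1) stopf("'fp' must be a matrix with >= 1 compound")
  if (is.null(radius0)) radius0 <- max(width, height) / 2
  m <- width * height
  d <- ncol(fp)
  # toroidal squared grid distances from each neuron to neuron 1, by offset
  rows <- ((seq_len(m) - 1L) %% height)
  cols <- ((seq_len(m) - 1L) %/% height)
  x <- fp
  storage.mode(x) <- "double"
  with_seed(child_seed(seed, "som"), {
    lo <- apply(x, 2, min); hi <- apply(x, 2, max)
    w <- matrix(stats::runif(m * d), m, d)
    w <- sweep(sweep(w, 2, hi - lo, "*"), 2, lo, "+")
    total <- epochs * nrow(x)
    step <- 0L
    for (e in seq_len(epochs)) {
      ord <- sample.int(nrow(x))
      for (i in ord) {
        frac <- step / max(1, total - 1)
        lr <- alpha[1] + (alpha[2] - alpha[1]) * frac
        sg <- radius0 + (1 - radius0) * frac
        xi <- x[i, ]
        d2 <- rowSums(w * w) - 2 * drop(w %*% xi)  # + const ||xi||^2
        bmu <- which.min(d2)
        dr <- abs(rows - rows[bmu]); dr <- pmin(dr, height - dr)
        dc <- abs(cols - cols[bmu]); dc <- pmin(dc, width - dc)
        h <- exp(-(dr * dr + dc * dc) / (2 * sg * sg))
        w <- w + (lr * h) * (matrix(xi, m, d, byrow = TRUE) - w)
        step <- step + 1L
      }
    }
  })
  structure(list(weights = w, width = width, height = height, periodic = TRUE,
                 bits = colnames(fp)),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("Periodic SOM: %d x %d grid, %d-dimensional neurons\n",
              x$width, x$height, ncol(x$weights)))
  invisible(x)
}

# Neuron index <-> (row, col); column-major, 1-based.
neuron_rc <- function(k, height) cbind(row = ((k - 1L) %% height) + 1L,
                                       col = ((k - 1L) %/% height) + 1L)

# Indices of the 8 toroidal neighbours of every neuron.
toroidal_neighbours <- function(width, height) {
  m <- width * height
  rc <- neuron_rc(seq_len(m), height)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nb <- matrix(0L, m, 8)
  for (j in seq_len(8)) {
    r <- ((rc[, "row"] - 1L + offs$dr[j]) %% height) + 1L
    c <- ((rc[, "col"] - 1L + offs$dc[j]) %% width) + 1L
    nb[, j] <- (c - 1L) * height + r
  }
  nb
}

#' U-matrix of a trained SOM
#'
#' For every neuron, the mean Euclidean distance between its weight vector and
#' those of its eight toroidal grid neighbours. Low heights mark basins of
#' mutually similar neurons (cluster interiors); high heights mark borders.
#'
#' @param grid a `som_grid`.
#' @return An object of class `umatrix`: a `height` x `width` numeric matrix
#'   of non-negative heights.
#' @export
compute_umatrix <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  w <- grid$weights
  nb <- toroidal_neighbours(grid$width, grid$height)
  h <- numeric(nrow(w))
  for (j in seq_len(8)) {
    dif <- w - w[nb[, j], , drop = FALSE]
    h <- h + sqrt(rowSums(dif * dif))
  }
  u <- matrix(h / 8, grid$height, grid$width)
  class(u) <- c("umatrix", class(u))
  u
}

#' Delineate compound clusters from a U-matrix
#'
#' Applies a height threshold to the U-matrix: neurons with height strictly
#' below the threshold form the foreground, whose 8-connected components on
#' the torus become the clusters (ids 1.., largest first). Every compound
#' inherits the cluster of its best-matching unit; compounds whose BMU lies on
#' a border (background) join the nearest foreground component by toroidal
#' grid distance.
#'
#' @param u a `umatrix`.
#' @param grid the `som_grid` it came from.
#' @param fp the fingerprint matrix the SOM was trained on.
#' @param threshold height threshold (> 0); `NULL` uses the 60th percentile of
#'   the heights.
#' @return An object of class `cluster_assignment`: list with
#'   `compound_cluster` (named integer vector), `neuron_cluster` (integer
#'   vector, 0 = background), `threshold`, `n_clusters`.
#' @export
delineate_clusters <- function(u, grid, fp, threshold = NULL) {
  stopifnot(inherits(grid, "som_grid"))
  heights <- as.numeric(u)
  if (is.null(threshold)) threshold <- as.numeric(stats::quantile(heights, 0.6))
  if (!is.numeric(threshold) || threshold <= 0) stopf("'threshold' must be > 0")
  fg <- which(heights < threshold)
  if (length(fg) == 0) stopf("threshold leaves zero foreground neurons; increase it")
  nb <- toroidal_neighbours(grid$width, grid$height)
  in_fg <- logical(length(heights)); in_fg[fg] <- TRUE
  edges <- matrix(integer(0), ncol = 2)
  for (j in seq_len(8)) {
    sel <- in_fg & in_fg[nb[, j]]
    if (any(sel)) edges <- rbind(edges, cbind(which(sel), nb[sel, j]))
  }
  gph <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(fg)))
  comp <- igraph::components(gph)
  memb <- stats::setNames(comp$membership, igraph::V(gph)$name)
  # relabel components: largest first, ids contiguous from 1
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  neuron_cluster <- integer(length(heights))
  neuron_cluster[fg] <- as.integer(relabel[as.character(memb[as.character(fg)])])
  # BMU per compound
  w <- grid$weights
  x <- fp; storage.mode(x) <- "double"
  w2 <- rowSums(w * w)
  cross <- x %*% t(w)
  bmu <- max.col(2 * cross - matrix(w2, nrow(x), length(w2), byrow = TRUE),
                 ties.method = "first")
  cc <- neuron_cluster[bmu]
  if (any(cc == 0L)) {
    rc <- neuron_rc(seq_along(heights), grid$height)
    fg_rc <- rc[fg, , drop = FALSE]
    for (i in which(cc == 0L)) {
      dr <- abs(fg_rc[, "row"] - rc[bmu[i], "row"]); dr <- pmin(dr, grid$height - dr)
      dc <- abs(fg_rc[, "col"] - rc[bmu[i], "col"]); dc <- pmin(dc, grid$width - dc)
      cc[i] <- neuron_cluster[fg[which.min(dr * dr + dc * dc)]]
    }
  }
  structure(list(
    compound_cluster = stats::setNames(as.integer(cc), rownames(fp)),
    neuron_cluster = neuron_cluster,
    threshold = threshold,
    n_clusters = length(sizes)
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Compound clustering: %d clusters over %d compounds (U-matrix threshold %.4g)\n",
              x$n_clusters, length(x$compound_cluster), x$threshold))
  print(table(cluster = x$compound_cluster))
  invisible(x)
}

#' Full chemical-space clustering pipeline
#'
#' Convenience wrapper: train the SOM, compute the U-matrix and delineate
#' clusters in one call.
#'
#' @inheritParams train_som
#' @inheritParams delineate_clusters
#' @return A `cluster_assignment`.
#' @export
cluster_compounds <- function(fp, width = 50L, height = 50L, epochs = 10L,
                              seed = 1L, threshold = NULL) {
  grid <- train_som(fp, width = width, height = height, epochs = epochs, seed = seed)
  u <- compute_umatrix(grid)
  delineate_clusters(u, grid, fp, threshold = threshold)
}
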