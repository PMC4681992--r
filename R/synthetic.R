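#' Specification of a synthetic growth-inhibition panel
#'
#' Describes an NCI60-like compound x cell line bioactivity panel with known
#' ground truth: planted chemical clusters in fingerprint space, tissues
#' grouping the cell lines, profiling views (one informative expression-like
#' view driving sensitivity, plus optional sparse uninformative views),
#' replicate measurements with per-pair experimental uncertainty, and a
#' fraction of missing matrix entries.
#'
#' The generative model for the noiseless potency of compound \eqn{c} on cell
#' line \eqn{l} is
#' \deqn{pGI_{50}(c,l) = \mu_c + a_{T(l)} + \gamma \, s_c^\top z_l}
#' where \eqn{\mu_c} is a compound potency drawn with sd
#' `effect_sizes["compound"]`, \eqn{a_T} a tissue offset with sd
#' `effect_sizes["tissue"]`, and the interaction couples a low-rank projection
#' \eqn{s_c} of the compound fingerprint to latent cell line factors
#' \eqn{z_l} that are also encoded (noisily) in the informative view, scaled so
#' the interaction term has sd `effect_sizes["interaction"]`. Pair-level noise
#' with sd `effect_sizes["noise"]` is added on top, and replicates scatter
#' around the pair value with a per-pair sd drawn from a gamma distribution
#' with mean `uncertainty_mean`.
#'
#' @param n_compounds,n_cell_lines,n_tissues,n_clusters panel dimensions;
#'   `n_tissues <= n_cell_lines` and `n_clusters <= n_compounds`.
#' @param fp_length fingerprint length in bits (default 256).
#' @param view_specs list of view descriptions, each a list with elements
#'   `name`, `n_features`, `informative` (flag) and `sparsity` (fraction of
#'   zero entries; only used for uninformative views).
#' @param missing_fraction fraction of the compound x cell line grid masked as
#'   unmeasured, in `[0, 1)`.
#' @param replicate_probs probabilities of 1, 2 or 3 replicates per pair.
#' @param uncertainty_mean mean of the per-pair replicate sd, in pGI50 units
#'   (default 0.27).
#' @param effect_sizes named numeric vector with entries `compound`, `tissue`,
#'   `interaction` and `noise` (standard deviations, pGI50 units).
#' @param latent_rank rank of the fingerprint-to-view latent coupling.
#' @param seed integer seed; all generator stages derive child seeds from it.
#'
#' @return An object of class `panel_spec`.
#' @seealso [generate_panel()], [generate_compound_library()]
#' @export
panel_spec <- function(n_compounds = 2000, n_cell_lines = 20, n_tissues = 9,
                       n_clusters = 4, fp_length = 256,
                       view_specs = list(
                         list(name = "expr", n_features = 20, informative = TRUE, sparsity = 0),
                         list(name = "mut", n_features = 40, informative = FALSE, sparsity = 0.98)
                       ),
                       missing_fraction = 0.07,
                       replicate_probs = c(0.68, 0.22, 0.10),
                       uncertainty_mean = 0.27,
                       effect_sizes = c(compound = 1, tissue = 0.5,
                                        interaction = 0.5, noise = 0.3),
                       latent_rank = 5, seed = 1L) {
  n_compounds <- check_count(n_compounds, "n_compounds")
  n_cell_lines <- check_count(n_cell_lines, "n_cell_lines", min = 2L)
  n_tissues <- check_count(n_tissues, "n_tissues")
  n_clusters <- check_count(n_clusters, "n_clusters")
  fp_length <- check_count(fp_length, "fp_length", min = 8L)
  if (n_tissues > n_cell_lines) stopf("'n_tissues' must not exceed 'n_cell_lines'")
  if (n_clusters > n_compounds) stopf("'n_clusters' must not exceed 'n_compounds'")
  check_fraction(missing_fraction, "missing_fraction")
  if (length(replicate_probs) != 3L || any(replicate_probs < 0) ||
      sum(replicate_probs) <= 0) {
    stopf("'replicate_probs' must be 3 non-negative weights over {1,2,3} replicates")
  }
  if (!is.numeric(uncertainty_mean) || uncertainty_mean < 0) {
    stopf("'uncertainty_mean' must be a non-negative sd in pGI50 units")
  }
  es <- effect_sizes
  needed <- c("compound", "tissue", "interaction", "noise")
  if (is.null(names(es)) && length(es) == 4L) names(es) <- needed
  if (!all(needed %in% names(es))) {
    stopf("'effect_sizes' must name %s", paste(needed, collapse = ", "))
  }
  if (any(es[needed] < 0)) stopf("'effect_sizes' must all be >= 0")
  for (vs in view_specs) {
    if (is.null(vs$name) || is.null(vs$n_features)) {
      stopf("each element of 'view_specs' needs 'name' and 'n_features'")
    }
    if (!is.null(vs$sparsity)) check_fraction(vs$sparsity, "sparsity", allow_one = FALSE)
  }
  latent_rank <- check_count(latent_rank, "latent_rank")
  structure(list(
    n_compounds = n_compounds, n_cell_lines = n_cell_lines,
    n_tissues = n_tissues, n_clusters = n_clusters, fp_length = fp_length,
    view_specs = view_specs, missing_fraction = missing_fraction,
    replicate_probs = replicate_probs / sum(replicate_probs),
    uncertainty_mean = uncertainty_mean, effect_sizes = es[needed],
    latent_rank = latent_rank, seed = as.integer(seed)
  ), class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("Synthetic panel spec: %d compounds x %d cell lines (%d tissues, %d planted clusters)\n",
              x$n_compounds, x$n_cell_lines, x$n_tissues, x$n_clusters))
  cat(sprintf("  fingerprints: %d bits; missing fraction %.3f; uncertainty mean %.2f\n",
              x$fp_length, x$missing_fraction, x$uncertainty_mean))
  cat(sprintf("  effect sds (compound/tissue/interaction/noise): %s\n",
              paste(format(x$effect_sizes), collapse = " / ")))
  cat(sprintf("  views: %s\n", paste(vapply(x$view_specs, function(v)
    sprintf("%s[%d%s]", v$name, v$n_features,
            if (isTRUE(v$informative)) ", informative" else ""), ""),
    collapse = ", ")))
  invisible(x)
}

compound_ids <- function(n) sprintf("CPD%05d", seq_len(n))
cell_line_ids <- function(n) sprintf("CL%02d", seq_len(n))

#' Generate a synthetic compound library with planted chemical clusters
#'
#' Draws a count-valued fingerprint matrix in which compounds belonging to the
#' same planted cluster share a cluster-specific bit-usage profile: each
#' cluster owns a block of high-rate bits (Poisson rate 3) while all other
#' bits fire at a low background rate, so that fingerprint-space clustering
#' (e.g. a SOM/U-matrix pipeline) can recover the labels.
#'
#' @param spec a [panel_spec()].
#' @return A list with `fingerprints` (n_compounds x fp_length integer matrix,
#'   rownames = compound ids) and `cluster_labels` (integer vector in
#'   `1:n_clusters`).
#' @export
generate_compound_library <- function(spec) {
  if (!inherits(spec, "panel_spec")) stopf("'spec' must be a panel_spec")
  with_seed(child_seed(spec$seed, "compound_library"), {
    n <- spec$n_compounds
    b <- spec$fp_length
    k <- spec$n_clusters
    labels <- sort(rep_len(seq_len(k), n))
    # cluster c owns a contiguous block of bits; rates: 3 inside, 0.05 outside
    block <- floor(b / k)
    rates <- matrix(0.05, k, b)
    for (c in seq_len(k)) {
      idx <- ((c - 1L) * block + 1L):(c * block)
      rates[c, idx] <- 3
    }
    fp <- matrix(stats::rpois(n * b, lambda = t(rates[labels, , drop = FALSE])),
                 nrow = n, ncol = b, byrow = TRUE)
    dimnames(fp) <- list(compound_ids(n), sprintf("bit%03d", seq_len(b)))
    list(fingerprints = fp, cluster_labels = labels)
  })
}

#' Generate a full synthetic bioactivity panel with ground truth
#'
#' Produces replicate-level bioactivity records, profiling views and the
#' ground truth (noiseless potency for *every* grid cell, including entries
#' masked as missing; planted cluster and tissue labels; latent coupling
#' weights). See [panel_spec()] for the generative model.
#'
#' @param spec a [panel_spec()].
#' @return A list of class `synthetic_panel` with elements:
#'   \describe{
#'     \item{records}{long data frame `(compound_id, cell_line_id,
#'       replicate_index, pGI50)` covering `(1 - missing_fraction)` of the grid.}
#'     \item{views}{named list of cell line x feature matrices.}
#'     \item{fingerprints}{the compound fingerprint matrix.}
#'     \item{tissues}{named character vector, cell line id -> tissue label.}
#'     \item{truth}{list with `cluster_labels`, `tissue_labels`, `noiseless`
#'       (full compound x cell line matrix), `sigma` (per-pair replicate sd,
#'       full grid), `latent` (compound scores, cell line factors, loadings),
#'       and `observed_mask`.}
#'   }
#' @export
generate_panel <- function(spec) {
  if (!inherits(spec, "panel_spec")) stopf("'spec' must be a panel_spec")
  lib <- generate_compound_library(spec)
  fp <- lib$fingerprints
  n_c <- spec$n_compounds
  n_l <- spec$n_cell_lines
  cl_ids <- cell_line_ids(n_l)
  # round-robin tissue assignment guarantees every tissue non-empty
  tissues <- stats::setNames(sprintf("T%02d", rep_len(seq_len(spec$n_tissues), n_l)), cl_ids)
  es <- spec$effect_sizes
  r <- spec$latent_rank

  with_seed(child_seed(spec$seed, "panel_effects"), {
    mu_c <- stats::rnorm(n_c, mean = 6, sd = es[["compound"]])
    a_t <- stats::setNames(stats::rnorm(spec$n_tissues, 0, es[["tissue"]]),
                           sprintf("T%02d", seq_len(spec$n_tissues)))
    z <- matrix(stats::rnorm(n_l * r), n_l, r)          # latent cell line factors
    b_load <- matrix(stats::rnorm(spec$fp_length * r, 0, 1 / sqrt(spec$fp_length)),
                     spec$fp_length, r)                 # fingerprint loadings
    s <- scale(fp) %*% b_load                           # compound scores
    s[is.na(s)] <- 0                                    # constant fp columns
    s <- scale(s)
    s[is.na(s)] <- 0
    inter <- (s %*% t(z)) * es[["interaction"]] / sqrt(r)
    noiseless <- outer(mu_c, rep(1, n_l)) + matrix(a_t[tissues], n_c, n_l, byrow = TRUE) + inter
    dimnames(noiseless) <- list(rownames(fp), cl_ids)
  })

  views <- with_seed(child_seed(spec$seed, "views"), {
    out <- list()
    for (vs in spec$view_specs) {
      p <- as.integer(vs$n_features)
      if (isTRUE(vs$informative)) {
        # informative view encodes the latent factors, lightly corrupted
        a <- matrix(stats::rnorm(r * p), r, p)
        m <- z %*% a + matrix(stats::rnorm(n_l * p, 0, 0.1), n_l, p)
      } else {
        sp <- if (is.null(vs$sparsity)) 0.95 else vs$sparsity
        m <- matrix(stats::rbinom(n_l * p, 1, 1 - sp), n_l, p)
      }
      dimnames(m) <- list(cl_ids, sprintf("%s_f%03d", vs$name, seq_len(p)))
      out[[vs$name]] <- m
    }
    out
  })

  with_seed(child_seed(spec$seed, "measurements"), {
    n_pairs <- n_c * n_l
    sigma <- if (spec$uncertainty_mean > 0) {
      matrix(stats::rgamma(n_pairs, shape = 4, rate = 4 / spec$uncertainty_mean), n_c, n_l)
    } else matrix(0, n_c, n_l)
    dimnames(sigma) <- dimnames(noiseless)
    pair_noise <- matrix(stats::rnorm(n_pairs, 0, es[["noise"]]), n_c, n_l)
    n_missing <- round(spec$missing_fraction * n_pairs)
    mask <- rep(TRUE, n_pairs)
    if (n_missing > 0) mask[sample.int(n_pairs, n_missing)] <- FALSE
    mask <- matrix(mask, n_c, n_l, dimnames = dimnames(noiseless))
    obs_idx <- which(mask)
    n_rep <- sample(1:3, length(obs_idx), replace = TRUE, prob = spec$replicate_probs)
    pair_mean <- noiseless[obs_idx] + pair_noise[obs_idx]
    pair_sigma <- sigma[obs_idx]
    total <- sum(n_rep)
    rec_pair <- rep(seq_along(obs_idx), n_rep)
    values <- pair_mean[rec_pair] + stats::rnorm(total, 0, pair_sigma[rec_pair])
    rc <- ((obs_idx - 1L) %% n_c) + 1L
    cc <- ((obs_idx - 1L) %/% n_c) + 1L
    records <- data.frame(
      compound_id = rownames(fp)[rc][rec_pair],
      cell_line_id = cl_ids[cc][rec_pair],
      replicate_index = unlist(lapply(n_rep, seq_len), use.names = FALSE),
      pGI50 = values,
      stringsAsFactors = FALSE
    )
  })

  structure(list(
    records = records,
    views = views,
    fingerprints = fp,
    tissues = tissues,
    truth = list(
      cluster_labels = lib$cluster_labels,
      tissue_labels = tissues,
      noiseless = noiseless,
      sigma = sigma,
      latent = list(compound_scores = s, cell_factors = z, loadings = b_load,
                    mu_compound = mu_c, tissue_offsets = a_t),
      observed_mask = mask
    ),
    spec = spec
  ), class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("Synthetic panel: %d records over %d (compound, cell line) pairs\n",
              nrow(x$records),
              nrow(unique(x$records[c("compound_id", "cell_line_id")]))))
  cat(sprintf("  %d compounds x %d cell lines; views: %s\n",
              nrow(x$fingerprints), length(x$tissues),
              paste(names(x$views), collapse = ", ")))
  invisible(x)
}
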