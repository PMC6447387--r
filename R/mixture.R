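#' Construct a profile mixture
#'
#' K weighted frequency profiles over the current alphabet (20 amino acids,
#' or recoding bins after [collapse_profiles()]): the object behind
#' empirical site-profile mixture models used to absorb compositional
#' heterogeneity across sites.  Classes are stored sorted by descending
#' weight so that label order is canonical.
#'
#' @param weights K non-negative reals; normalized to sum to 1.
#' @param profiles K x n_states matrix with named columns; rows normalized.
#' @param loglik achieved objective (see [fit_mixture()]), or `NA`.
#' @param seed integer seed used in fitting, or `NA`.
#' @return object of class `profile_mixture`.
#' @export
profile_mixture <- function(weights, profiles, loglik = NA_real_,
                            seed = NA_integer_) {
  profiles <- as.matrix(profiles)
  if (length(weights) != nrow(profiles))
    stop("one weight per profile required", call. = FALSE)
  if (any(weights < 0) || any(profiles < 0))
    stop("weights and profiles must be non-negative", call. = FALSE)
  weights <- weights / sum(weights)
  profiles <- profiles / rowSums(profiles)
  ord <- order(-weights)
  weights <- weights[ord]
  profiles <- profiles[ord, , drop = FALSE]
  rownames(profiles) <- paste0("class", seq_len(nrow(profiles)))
  structure(list(K = nrow(profiles), weights = unname(weights),
                 profiles = profiles, loglik = loglik, seed = seed),
            class = "profile_mixture")
}

#' @export
print.profile_mixture <- function(x, ...) {
  cat(sprintf("profile_mixture: %d classes over %d states; loglik = %s\n",
              x$K, ncol(x$profiles),
              if (is.na(x$loglik)) "NA" else sprintf("%.4f", x$loglik)))
  invisible(x)
}

## Per-site state counts over taxa: n_sites x n_states matrix.
site_state_counts <- function(a) {
  k <- length(a$alphabet)
  idx <- matrix(match(a$matrix, a$alphabet), nrow = length(a$taxa))
  out <- matrix(0L, a$n_sites, k, dimnames = list(NULL, a$alphabet))
  for (j in seq_len(a$n_sites))
    out[j, ] <- tabulate(idx[, j], nbins = k)
  out
}

#' Estimate a dataset-specific amino-acid profile mixture by EM
#'
#' Fits a K-class multinomial mixture to the per-site amino-acid count
#' vectors of an alignment: each column is assumed drawn from one of K
#' latent frequency profiles.  The E-step computes class responsibilities
#' per site; the M-step updates weights and profiles with a Dirichlet(0.5)
#' pseudocount added to profile counts, so the iteration maximizes the
#' penalized log-likelihood (log-likelihood plus log-prior), which is
#' non-decreasing every iteration.  Initialization is k-means++-style on
#' normalized count vectors.  Sites with no non-missing cells are excluded.
#'
#' @param a an [aa_alignment].
#' @param K number of classes (>= 1).
#' @param max_iter iteration cap.
#' @param tol stop when the objective gain drops below this.
#' @param seed integer seed (initialization is stochastic).
#' @return a [profile_mixture]; extra fields `loglik_trace` (objective per
#'   iteration), `data_loglik` (unpenalized, final), `n_iter`.
#' @export
fit_mixture <- function(a, K, max_iter = 500L, tol = 1e-6, seed = 1L) {
  stopifnot(inherits(a, "aa_alignment"), K >= 1L)
  counts <- site_state_counts(a)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  n <- nrow(counts)
  if (K > n) stop("K exceeds the number of informative sites", call. = FALSE)
  k_states <- ncol(counts)
  alpha <- 0.5                       # Dirichlet pseudocount per state
  set.seed(seed)

  norm <- counts / rowSums(counts)
  ## k-means++ seeding on normalized count vectors
  centers <- matrix(0, K, k_states)
  first <- sample.int(n, 1L)
  centers[1L, ] <- norm[first, ]
  if (K > 1L) {
    d2 <- rowSums((norm - matrix(centers[1L, ], n, k_states, TRUE))^2)
    for (kk in 2:K) {
      pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else
        sample.int(n, 1L)
      centers[kk, ] <- norm[pick, ]
      d2 <- pmin(d2, rowSums((norm - matrix(centers[kk, ], n, k_states,
                                            TRUE))^2))
    }
  }
  profiles <- centers + 0.01          # smooth away zero frequencies
  profiles <- profiles / rowSums(profiles)
  weights <- rep(1 / K, K)

  objective <- function(profiles, weights) {
    lp <- counts %*% t(log(profiles))           # n x K
    lp <- sweep(lp, 2L, log(weights), `+`)
    mx <- apply(lp, 1L, max)
    dl <- sum(mx + log(rowSums(exp(lp - mx))))
    list(data = dl,
         pen = dl + alpha * sum(log(profiles)))
  }

  trace <- numeric(0)
  prev <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    lp <- counts %*% t(log(profiles))
    lp <- sweep(lp, 2L, log(weights), `+`)
    mx <- apply(lp, 1L, max)
    w <- exp(lp - mx)
    rs <- rowSums(w)
    resp <- w / rs
    obj <- objective(profiles, weights)
    if (!is.finite(obj$pen))
      stop(sprintf("non-finite likelihood at iteration %d", it),
           call. = FALSE)
    trace <- c(trace, obj$pen)
    if (it > 1L && obj$pen - prev < tol) break
    prev <- obj$pen
    weights <- colSums(resp) / n
    weights <- pmax(weights, 1e-12)
    weights <- weights / sum(weights)
    num <- t(resp) %*% counts + alpha
    profiles <- num / rowSums(num)
  }
  final <- objective(profiles, weights)
  out <- profile_mixture(weights, profiles, loglik = final$pen, seed = seed)
  ## class order changed by canonical sorting; reorder nothing else exposed
  out$loglik_trace <- trace
  out$data_loglik <- final$data
  out$n_iter <- length(trace)
  out
}

#' Export a mixture as a model-definition block
#'
#' Writes a NEXUS-style frequency-mixture definition loadable as a custom
#' mixture by common ML tree software: one `frequency` line per class and
#' an `FMIX` line combining them with their weights.  Profiles containing
#' an exact zero are smoothed by 1e-6 and renormalized with a warning.
#'
#' @param m a [profile_mixture].
#' @param name model name used in the block.
#' @param path optional file to write; if `NULL` the text is returned only.
#' @return character vector of lines, invisibly if `path` given.
#' @export
export_mixture <- function(m, name, path = NULL) {
  stopifnot(inherits(m, "profile_mixture"))
  profiles <- m$profiles
  if (any(profiles == 0)) {
    warning("zero frequencies smoothed by 1e-6 and renormalized",
            call. = FALSE)
    profiles <- profiles + 1e-6
    profiles <- profiles / rowSums(profiles)
  }
  cls <- sprintf("%sC%d", name, seq_len(m$K))
  lines <- c(
    "#nexus",
    "begin models;",
    sprintf("  frequency %s = %s;", cls,
            apply(profiles, 1L, function(p)
              paste(sprintf("%.10g", p), collapse = " "))),
    sprintf("  frequency %s = FMIX{%s};", name,
            paste(sprintf("%s:1:%.10g", cls, m$weights), collapse = ",")),
    "end;")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a mixture model-definition block
#'
#' Inverse of [export_mixture()]; state labels are not stored in the block,
#' so `alphabet` supplies the column names.
#'
#' @param path file path (or character vector of lines via `text`).
#' @param text optional lines, used instead of `path`.
#' @param alphabet state labels for profile columns.
#' @return a [profile_mixture].
#' @export
parse_mixture <- function(path = NULL, text = NULL, alphabet = AA_ALPHABET) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  freq <- regmatches(lines, regexec(
    "frequency\\s+(\\S+)\\s*=\\s*([-0-9. eE+]+);", lines))
  freq <- freq[lengths(freq) == 3L]
  profs <- lapply(freq, function(f)
    as.numeric(strsplit(trimws(f[[3L]]), "\\s+")[[1L]]))
  names(profs) <- vapply(freq, `[[`, "", 2L)
  mix <- regmatches(lines, regexec("FMIX\\{([^}]*)\\}", lines))
  mix <- mix[lengths(mix) == 2L]
  if (!length(mix)) stop("no FMIX line found", call. = FALSE)
  comps <- strsplit(mix[[1L]][[2L]], ",")[[1L]]
  parts <- strsplit(comps, ":")
  cls <- vapply(parts, `[`, "", 1L)
  w <- as.numeric(vapply(parts, `[`, "", 3L))
  pm <- do.call(rbind, profs[cls])
  if (ncol(pm) != length(alphabet))
    stop(sprintf("profiles have %d states, alphabet has %d",
                 ncol(pm), length(alphabet)), call. = FALSE)
  colnames(pm) <- alphabet
  profile_mixture(w, pm)
}

#' Dump mixture weights and profiles as TSV
#'
#' @param m a [profile_mixture].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mixture_tsv <- function(m, path) {
  df <- data.frame(class = rownames(m$profiles), weight = m$weights,
                   m$profiles, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
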