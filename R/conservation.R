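#' Configuration for pathway relative-rate tests
#'
#' @param min_pathway_size Minimum orthologs per pathway; pathways at or
#'   above this size are tested (default 11, i.e. "more than ten").
#' @param B Bootstrap resamples for the percentile p-value (default 10000).
#' @param alpha Significance level reported alongside (default 0.05).
#' @return A list of class `rate_test_config`.
#' @export
rate_test_config <- function(min_pathway_size = 11, B = 10000,
                             alpha = 0.05) {
  stopifnot(B >= 100, alpha > 0, alpha < 1)
  structure(list(min_pathway_size = min_pathway_size, B = B, alpha = alpha),
            class = "rate_test_config")
}

#' Relative-rate test of expression divergence between two lineages
#'
#' For each gene computes the squared log-expression deviation of each focal
#' organism from the shared outgroup reference,
#' `u_g = (z1_g - zO_g)^2` and `v_g = (z2_g - zO_g)^2`, and contrasts their
#' means: `delta = mean(u) - mean(v)`. A positive delta means org1 diverged
#' faster. The two-sided p-value is a recentred percentile bootstrap over
#' genes: the bootstrap distribution of delta is shifted to zero and the
#' observed delta compared against it.
#'
#' @param em Log-scale matrix or `expression_matrix` with log2 layer.
#' @param genes Row ids forming the gene set (e.g. one pathway).
#' @param org1,org2 The two lineages compared.
#' @param outgroup Reference organism.
#' @param B Bootstrap resamples (default 10000).
#' @param seed Random seed.
#' @return List with `delta`, `p.value`, `direction` (`"org1 faster"`,
#'   `"org2 faster"` or `"equal"`), `n_genes`.
#' @export
relative_rate_test <- function(em, genes, org1, org2, outgroup, B = 10000,
                               seed = 1) {
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  miss <- setdiff(c(org1, org2, outgroup), colnames(lg))
  if (length(miss)) stop("organism(s) not in matrix: ",
                         paste(miss, collapse = ", "))
  genes <- intersect(genes, rownames(lg))
  u <- (lg[genes, org1] - lg[genes, outgroup])^2
  v <- (lg[genes, org2] - lg[genes, outgroup])^2
  dvec <- u - v
  n <- length(dvec)
  delta <- mean(dvec)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
  dstar <- colMeans(matrix(dvec[idx], n, B)) - delta  # recentred null draws
  p <- 2 * min((1 + sum(dstar >= delta)) / (B + 1),
               (1 + sum(dstar <= delta)) / (B + 1))
  list(delta = delta, p.value = min(p, 1),
       direction = if (delta > 0) paste(org1, "faster")
                   else if (delta < 0) paste(org2, "faster") else "equal",
       n_genes = n)
}

#' Run relative-rate tests over all qualifying pathways
#'
#' Applies [relative_rate_test()] to every pathway with at least
#' `min_pathway_size` orthologs present in the matrix; smaller pathways are
#' skipped with a reason.
#'
#' @param em Log-scale matrix or `expression_matrix` with log2 layer.
#' @param pathways Named list: pathway id -> character vector of row ids.
#' @param org1,org2,outgroup Organism ids as in [relative_rate_test()].
#' @param config A `rate_test_config`.
#' @param seed Random seed (incremented per pathway for independence).
#' @return Data frame with one row per pathway: `pathway`, `n_genes`,
#'   `delta`, `p.value`, `significant`, `direction`; skipped pathways are in
#'   attribute `"skipped"`.
#' @export
pathway_rate_tests <- function(em, pathways, org1, org2, outgroup,
                               config = rate_test_config(), seed = 1) {
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  sizes <- vapply(pathways, function(g) length(intersect(g, rownames(lg))),
                  integer(1))
  ok <- sizes >= config$min_pathway_size
  skipped <- data.frame(pathway = names(pathways)[!ok],
                        reason = sprintf("only %d orthologs (< %d)",
                                         sizes[!ok],
                                         config$min_pathway_size),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_along(pathways)[ok], function(i) {
    rt <- relative_rate_test(lg, pathways[[i]], org1, org2, outgroup,
                             B = config$B, seed = seed + i)
    data.frame(pathway = names(pathways)[i], n_genes = rt$n_genes,
               delta = rt$delta, p.value = rt$p.value,
               significant = rt$p.value < config$alpha,
               direction = rt$direction, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(pathway = character(), n_genes = integer(),
                         delta = numeric(), p.value = numeric(),
                         significant = logical(), direction = character())
  attr(out, "skipped") <- skipped
  out
}

#' Inter-organism correlation matrix and its inverse
#'
#' Builds the Pearson correlation matrix R of the organisms' log-expression
#' columns and inverts it. Near-singular matrices (condition number above
#' `cond_max`) are ridge-stabilized by adding `lambda * I` with
#' `lambda = 1e-6 * trace(R)/m`, with a warning.
#'
#' @param em Log-scale matrix or `expression_matrix` with log2 layer.
#' @param organisms Optional subset of organism columns.
#' @param cond_max Condition-number threshold triggering the ridge
#'   (default 1e8).
#' @return List with `R`, `Rinv`, `ridged` (logical) and `lambda`.
#' @export
corr_mat_inv <- function(em, organisms = NULL, cond_max = 1e8) {
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  if (!is.null(organisms)) lg <- lg[, organisms, drop = FALSE]
  if (ncol(lg) < 3) stop("need at least 3 organisms")
  if (nrow(lg) < 50) stop("need at least 50 genes")
  R <- stats::cor(lg)
  lambda <- 0; ridged <- FALSE
  if (kappa(R, exact = TRUE) > cond_max) {
    lambda <- 1e-6 * sum(diag(R)) / ncol(R)
    R <- R + diag(lambda, ncol(R))
    ridged <- TRUE
    warning("near-singular correlation matrix; ridge ", signif(lambda, 3),
            " added to the diagonal")
  }
  Rinv <- tryCatch(solve(R),
                   error = function(e) stop("correlation matrix singular ",
                                            "even after ridge: ",
                                            conditionMessage(e)))
  list(R = R, Rinv = Rinv, ridged = ridged, lambda = lambda)
}

#' Per-gene expression-divergence quadratic form Q
#'
#' Centers each gene's log-expression values across organisms and computes
#' the quadratic form `Q_g = z_g' R^-1 z_g` against the inverse
#' inter-organism correlation matrix. Large Q means large coordinated
#' divergence; Q = 0 for a gene identical in every organism. The associated
#' degrees of freedom are `nu = m - 1` (one lost to centering).
#'
#' @param em Log-scale matrix or `expression_matrix` with log2 layer.
#' @param Rinv Inverse correlation matrix from [corr_mat_inv()] (columns
#'   must match its organisms).
#' @return Named numeric vector of Q values with attribute `"nu"`.
#' @export
est_q <- function(em, Rinv) {
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  orgs <- colnames(Rinv)
  lg <- lg[, orgs, drop = FALSE]
  z <- lg - rowMeans(lg)
  Q <- rowSums((z %*% Rinv) * z)
  Q[Q < 0] <- 0  # numerical guard
  attr(Q, "nu") <- ncol(lg) - 1
  Q
}

#' Fit the gamma prior of expression conservation by maximum likelihood
#'
#' Models the per-gene divergence as `Q | W ~ Gamma(nu/2, rate = W)` (i.e.
#' `(1/(2W)) * chi^2_nu`) with gene-specific conservation
#' `W ~ Gamma(alpha, rate = beta)`. Marginally Q then follows a compound
#' gamma (beta-prime type) density; `alpha` and `beta` are estimated by
#' numerical maximum likelihood with moment-based initialization from
#' `E[Q] = nu*beta / (2*(alpha-1))` and
#' `E[Q^2] = nu*(nu+2)*beta^2 / (4*(alpha-1)*(alpha-2))`.
#'
#' @param Q Numeric vector of per-gene quadratic forms (>= 200 positive
#'   values required).
#' @param nu Degrees of freedom (from [est_q()]).
#' @return List with `alpha`, `beta`, `logLik`, `convergence`.
#' @export
fit_gamma_prior <- function(Q, nu) {
  Q <- Q[is.finite(Q) & Q > 0]
  if (length(Q) < 200)
    stop("need at least 200 genes with positive Q to fit the prior")
  if (stats::sd(Q) < 1e-12 * mean(Q))
    stop("degenerate Q distribution (all values equal); cannot fit prior")
  n <- length(Q); slq <- sum(log(Q))
  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -(n * (a * log(b) + lgamma(a + nu / 2) - lgamma(nu / 2) - lgamma(a)) +
        (nu / 2 - 1) * slq - (a + nu / 2) * sum(log(b + Q)))
  }
  m1 <- mean(Q); m2 <- mean(Q^2)
  r <- m2 / m1^2
  a0 <- (2 * r * nu - nu - 2) / (r * nu - nu - 2)
  if (!is.finite(a0) || a0 <= 0.1) a0 <- 2
  b0 <- 2 * max(a0 - 1, 0.5) * m1 / nu
  fit <- stats::optim(log(c(a0, b0)), negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("gamma-prior fit did not converge (optim code ", fit$convergence,
         "); initial values alpha=", signif(a0, 4), " beta=", signif(b0, 4))
  alpha <- exp(fit$par[1]); beta <- exp(fit$par[2])
  if (alpha <= 1)
    warning("fitted alpha <= 1: prior on 1/W has no finite mean ",
            "(heavy-tailed divergence)")
  list(alpha = alpha, beta = beta, logLik = -fit$value,
       convergence = fit$convergence)
}

#' Posterior mean expression conservation
#'
#' With the gamma prior `W ~ Gamma(alpha, rate = beta)` and likelihood
#' `Q | W ~ Gamma(nu/2, rate = W)`, the posterior is conjugate:
#' `W | Q ~ Gamma(alpha + nu/2, rate = beta + Q)`. Reports the posterior
#' mean `(alpha + nu/2) / (beta + Q)`, strictly decreasing in Q.
#'
#' @param Q Per-gene quadratic forms.
#' @param alpha,beta Gamma prior hyper-parameters.
#' @param nu Degrees of freedom.
#' @return Numeric vector of posterior mean W (names preserved).
#' @export
posterior_w <- function(Q, alpha, beta, nu) {
  stopifnot(alpha > 0, beta > 0)
  (alpha + nu / 2) / (beta + Q)
}

#' Call genes under high and low expression selection pressure
#'
#' HSG = genes whose posterior conservation W lies above the upper
#' `1 - q` empirical quantile; LSG = below the lower `q` quantile.
#'
#' @param W Named numeric vector of posterior conservation values.
#' @param q Tail fraction (default 0.05).
#' @return List of class `conservation_calls` with `hsg`, `lsg` (gene ids)
#'   and `thresholds` (realized lower/upper cutoffs).
#' @export
call_hsg_lsg <- function(W, q = 0.05) {
  stopifnot(length(W) >= 20, q > 0, q < 0.5)
  if (stats::sd(W) == 0) {
    warning("all conservation values equal; no HSG/LSG called")
    return(structure(list(hsg = character(0), lsg = character(0),
                          thresholds = c(lower = NA_real_,
                                         upper = NA_real_)),
                     class = "conservation_calls"))
  }
  lo <- stats::quantile(W, q, names = FALSE)
  hi <- stats::quantile(W, 1 - q, names = FALSE)
  structure(list(hsg = names(W)[W > hi], lsg = names(W)[W < lo],
                 thresholds = c(lower = lo, upper = hi)),
            class = "conservation_calls")
}

#' Summarize conservation by pathway
#'
#' @param W Named numeric vector of posterior conservation values.
#' @param pathways Named list: pathway id -> gene/orthogroup ids.
#' @param min_size Minimum genes with W per pathway (default 11).
#' @return Data frame `pathway`, `n`, `mean_w`, `median_w`, `rank` (1 =
#'   highest mean conservation); undersized pathways are dropped and listed
#'   in attribute `"skipped"`.
#' @export
pathway_w_distributions <- function(W, pathways, min_size = 11) {
  rows <- lapply(names(pathways), function(p) {
    w <- W[intersect(pathways[[p]], names(W))]
    data.frame(pathway = p, n = length(w),
               mean_w = if (length(w)) mean(w) else NA_real_,
               median_w = if (length(w)) stats::median(w) else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  keep <- df$n >= min_size
  out <- df[keep, , drop = FALSE]
  out$rank <- rank(-out$mean_w, ties.method = "min")
  attr(out, "skipped") <- df$pathway[!keep]
  rownames(out) <- NULL
  out
}

#' Estimate expression conservation for every gene
#'
#' End-to-end wrapper: builds the inter-organism correlation matrix and its
#' inverse, computes per-gene divergence Q, fits the gamma prior, and
#' reports posterior conservation W with HSG/LSG calls.
#'
#' @param em Log-scale matrix or `expression_matrix` with log2 layer.
#' @param organisms Optional subset of organism columns.
#' @param q Tail fraction for HSG/LSG calling (default 0.05).
#' @return Object of class `conservation_fit`: list with `R`, `Rinv`, `Q`,
#'   `nu`, `alpha`, `beta`, `W`, `calls`.
#' @export
estimate_conservation <- function(em, organisms = NULL, q = 0.05) {
  cm <- corr_mat_inv(em, organisms)
  Q <- est_q(em, cm$Rinv)
  nu <- attr(Q, "nu")
  prior <- fit_gamma_prior(Q, nu)
  W <- posterior_w(Q, prior$alpha, prior$beta, nu)
  names(W) <- names(Q)
  structure(list(R = cm$R, Rinv = cm$Rinv, Q = Q, nu = nu,
                 alpha = prior$alpha, beta = prior$beta, W = W,
                 calls = call_hsg_lsg(W, q)),
            class = "conservation_fit")
}

#' @export
print.conservation_fit <- function(x, ...) {
  cat("Expression conservation fit:", length(x$W), "genes,",
      ncol(x$R), "organisms (nu =", x$nu, ")\n")
  cat(sprintf("  gamma prior: alpha = %.3f, beta = %.3f\n", x$alpha, x$beta))
  cat(sprintf("  W range: %.3f - %.3f; HSG > %.3f (n=%d), LSG < %.3f (n=%d)\n",
              min(x$W), max(x$W), x$calls$thresholds["upper"],
              length(x$calls$hsg), x$calls$thresholds["lower"],
              length(x$calls$lsg)))
  invisible(x)
}

#' Read a gene-to-pathway annotation table
#'
#' Expects a TSV with columns `pathway`, `name` (optional) and `gene` (one
#' row per pathway-gene pair; `gene` may hold orthogroup ids).
#'
#' @param path Path to the TSV file.
#' @return Named list pathway id -> character vector of gene/orthogroup
#'   ids, with pathway names in attribute `"pathway_names"`.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway", "gene") %in% names(df)))
    stop("pathway table needs columns 'pathway' and 'gene'")
  out <- split(df$gene, df$pathway)
  if (any(lengths(out) == 0)) stop("empty pathway gene set")
  if ("name" %in% names(df))
    attr(out, "pathway_names") <-
      vapply(split(df$name, df$pathway), `[`, character(1), 1)
  out
}
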