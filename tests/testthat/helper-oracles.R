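## Independent brute-force oracles used to cross-check the implementation.
## These deliberately avoid the code paths (and, where possible, the stats
## functions) they validate.

## Small, fast phenotype for rendering tests.
small_params <- function(...) {
  args <- list(...)
  if (is.null(args$n_mito_components)) args$n_mito_components <- 6
  do.call(cell_phenotype_params,
          c(list(canvas = 96, cell_radius = 34, nucleus_radius = 9), args))
}

## Greedy Ward agglomeration by direct minimization of the within-cluster
## sum-of-squares increase; returns the merge member sets and merge costs.
ward_brute_force <- function(x) {
  cl <- as.list(seq_len(nrow(x)))
  merges <- list()
  costs <- numeric(0)
  while (length(cl) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      a <- x[cl[[i]], , drop = FALSE]
      b <- x[cl[[j]], , drop = FALSE]
      cost <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
        sum((colMeans(a) - colMeans(b))^2)
      if (cost < best_cost) {
        best_cost <- cost
        best <- c(i, j)
      }
    }
    merges[[length(merges) + 1]] <- sort(c(cl[[best[1]]], cl[[best[2]]]))
    costs <- c(costs, best_cost)
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  list(merges = merges, costs = costs)
}

## Member sets of each hclust merge, for comparison with the oracle.
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[m]] <- sort(c(get(hc$merge[m, 1]), get(hc$merge[m, 2])))
  }
  sets
}

## Two-sided Fisher exact p by full hypergeometric enumeration over all
## tables with the observed margins.
fisher_enumerate <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1), numeric(1))
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mann_whitney_enumerate <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals)
  m <- length(a)
  u_of <- function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(m))
  us <- apply(utils::combn(n, m), 2, u_of)
  mu <- m * (n - m) / 2
  min(1, sum(abs(us - mu) >= abs(u_obs - mu) - 1e-9) / length(us))
}

## Tie-corrected Spearman rho via the classical rank formula.
spearman_rank_formula <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  stats::cov(rx, ry) / sqrt(stats::var(rx) * stats::var(ry))
}

## Detection percentage of one feature subset, straight from the definition.
detection_of_subset <- function(flags, subset) {
  100 * mean(apply(flags[, subset, drop = FALSE], 1, any))
}

## A derived-feature table for two runs written from first principles.
toy_derived_table <- function() {
  data.frame(
    donor_id = c("P1", "HCa", "P2", "HCb"),
    run_id = c("r1", "r1", "r2", "r2"),
    role = c("patient", "control", "patient", "control"),
    n_cells = 100L,
    delta_mmp = c(320, 400, 520, 400),
    mmp = c(500, 500, 600, 500),
    nao_intensity = c(30000, 30000, 39000, 30000),
    tmrm_area_um2 = c(60, 60, 84, 60),
    form_factor = c(1.8, 2.0, 2.0, 2.0),
    mitosox_cyto_intensity = c(18750, 15000, 15000, 15000),
    fccp_ratio = c(4, 4, 6.4, 4),
    stringsAsFactors = FALSE)
}
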