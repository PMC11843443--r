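# Co-localization excess via resampling (two comparison strategies) and
# the co-function expectation statistic.

# Sample `n` distinct unordered pairs, uniformly, from a pool described by
# an index space of size `pool_size`, and return the sampled pair indices.
.sample_pair_indices <- function(pool_size, n) {
  sample.int(pool_size, n, replace = FALSE)
}

#' Co-localization excess of same-branch protein pairs
#'
#' For each target branch, counts the within-branch protein pairs that share
#' a compartment (`co_intra` out of `Intra_num` pairs) and compares against
#' repeated samples, of exactly `Intra_num` pairs each, drawn without
#' replacement from a comparison pool: strategy `A` pools pairs between the
#' target branch and all other branches; strategy `B` pools all unordered
#' pairs in the dataset. The per-iteration excess is
#' `(co_intra - co_sample) / co_sample * 100`; iterations whose sample
#' contains no co-localized pair are excluded from the mean and counted.
#'
#' Only proteins localized to a single compartment should be supplied
#' (the usual filter for this statistic).
#'
#' @param branch Named character/factor vector, branch per protein.
#' @param compartment Named character vector, the single called compartment
#'   per protein (same names as `branch`).
#' @param strategy `"A"` (target vs other branches) or `"B"` (target vs all
#'   pairs).
#' @param n_iter Number of resampling iterations (default 100).
#' @param seed Optional integer seed for reproducibility.
#' @return data.frame with one row per branch: `branch`, `n_proteins`,
#'   `intra_num`, `inter_num`, `co_intra`, `mean_excess`, `sd_excess`,
#'   `n_iter_used`, `n_zero_denominator`; per-iteration excesses are
#'   attached as the `iterations` attribute (a named list).
#' @export
colocalization_excess <- function(branch, compartment,
                                  strategy = c("A", "B"),
                                  n_iter = 100, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  ids <- names(branch)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(compartment))))
  comp <- as.integer(factor(compartment[ids]))
  br <- as.character(branch)
  branches <- intersect(branch_labels(), unique(br))
  if (length(branches) == 0) branches <- sort(unique(br))

  n_all <- length(ids)
  res <- vector("list", length(branches))
  iters <- vector("list", length(branches))
  names(iters) <- branches

  for (bi in seq_along(branches)) {
    b <- branches[bi]
    in_b <- which(br == b)
    out_b <- which(br != b)
    n_b <- length(in_b)
    if (n_b < 2) {
      res[[bi]] <- data.frame(branch = b, n_proteins = n_b,
                              intra_num = NA_integer_, inter_num = NA_real_,
                              co_intra = NA_integer_, mean_excess = NA_real_,
                              sd_excess = NA_real_, n_iter_used = 0L,
                              n_zero_denominator = 0L)
      next
    }
    intra_num <- n_b * (n_b - 1) / 2
    # within-branch co-localized pairs from the compartment size table
    cnt <- tabulate(comp[in_b])
    co_intra <- sum(cnt * (cnt - 1) / 2)

    comp_b <- comp[in_b]
    comp_o <- comp[out_b]
    if (strategy == "A") {
      inter_num <- n_b * length(out_b)
    } else {
      inter_num <- n_all * (n_all - 1) / 2
    }
    n_draw <- intra_num
    if (n_draw > inter_num) {
      warning("branch ", b, ": intra_num (", intra_num,
              ") exceeds the comparison pool (", inter_num,
              "); sampling the full pool instead")
      n_draw <- inter_num
    }
    draw <- if (strategy == "A") {
      function() {
        k <- .sample_pair_indices(inter_num, n_draw)
        i <- ((k - 1) %% n_b) + 1
        j <- ((k - 1) %/% n_b) + 1
        sum(comp_b[i] == comp_o[j])
      }
    } else {
      function() {
        k <- .sample_pair_indices(inter_num, n_draw)
        # map linear index to an unordered pair (i < j) over all proteins
        j <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
        over <- k <= (j - 1) * (j - 2) / 2
        j[over] <- j[over] - 1
        under <- k > j * (j - 1) / 2
        j[under] <- j[under] + 1
        i <- k - (j - 1) * (j - 2) / 2
        sum(comp[i] == comp[j])
      }
    }
    exc <- numeric(n_iter)
    zero <- logical(n_iter)
    for (it in seq_len(n_iter)) {
      # rescale the sampled co-count to the intra_num scale (no-op unless
      # the pool was smaller than intra_num)
      co_s <- draw() * intra_num / n_draw
      if (co_s == 0) {
        zero[it] <- TRUE
        exc[it] <- NA_real_
      } else {
        exc[it] <- 100 * (co_intra - co_s) / co_s
      }
    }
    used <- exc[!zero]
    res[[bi]] <- data.frame(branch = b, n_proteins = n_b,
                            intra_num = intra_num, inter_num = inter_num,
                            co_intra = co_intra,
                            mean_excess = if (length(used)) mean(used) else
                              NA_real_,
                            sd_excess = if (length(used) > 1) sd(used) else
                              NA_real_,
                            n_iter_used = length(used),
                            n_zero_denominator = sum(zero))
    iters[[b]] <- exc
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "iterations") <- iters
  attr(out, "strategy") <- strategy
  out
}

#' Trend of co-localization excess across branch age
#'
#' Pearson correlation of mean per-branch excess against the branch index
#' (oldest to youngest), with the fitted regression line.
#'
#' @param mean_excess Named numeric vector of mean excess per branch (names
#'   are branch labels); NA entries are dropped.
#' @return list with `r`, `p_value`, `slope`, `intercept`, `n`; with
#'   constant means the correlation is undefined and `r` is NA with
#'   `degenerate = TRUE`.
#' @export
excess_vs_branch_regression <- function(mean_excess) {
  keep <- !is.na(mean_excess)
  y <- mean_excess[keep]
  x <- branch_index(names(y))
  if (length(y) < 3) stop("need >= 3 branches with defined mean excess")
  if (sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, slope = 0,
                intercept = unname(y[1]), n = length(y), degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(y), degenerate = FALSE)
}

#' Co-function expectation and excess per age group
#'
#' A protein pair is co-functional when their pathway sets intersect. The
#' null co-function probability is `p_co = sum_i P(K_i)^2`, where `P(K_i)`
#' is the fraction of all annotated proteins carrying pathway `K_i`
#' (single-membership arithmetic; with multi-pathway proteins this is the
#' conventional simplification and can exceed the true pair probability).
#' Per group, `E = C(n, 2) * p_co` and `O` counts observed co-functional
#' pairs; the excess is `(O - E) / E`.
#'
#' @param pathways Named list mapping protein id to a character vector of
#'   pathway ids (>= 1 each).
#' @param groups Named character/factor vector of group labels per protein;
#'   names must be annotated in `pathways`.
#' @return list with `p_co` and `table` (data.frame: group, n_proteins,
#'   expected, observed, excess); groups with < 2 proteins are skipped.
#' @export
cofunction_expectation <- function(pathways, groups) {
  ids <- names(groups)
  stopifnot(!is.null(ids), all(ids %in% names(pathways)))
  # P(K_i) over ALL annotated proteins
  n_tot <- length(pathways)
  pw_of <- unlist(pathways, use.names = FALSE)
  prot_of <- rep(names(pathways), lengths(pathways))
  p_k <- table(pw_of) / n_tot
  p_co <- sum(p_k^2)

  pw_levels <- names(p_k)
  inc <- Matrix::sparseMatrix(
    i = match(prot_of, names(pathways)),
    j = match(pw_of, pw_levels), x = 1,
    dims = c(n_tot, length(pw_levels)),
    dimnames = list(names(pathways), pw_levels))

  grp <- factor(groups)
  rows <- lapply(levels(grp), function(g) {
    members <- ids[grp == g]
    n <- length(members)
    if (n < 2) {
      message("cofunction_expectation: skipping group '", g,
              "' with < 2 proteins")
      return(NULL)
    }
    e <- n * (n - 1) / 2 * p_co
    sub <- inc[members, , drop = FALSE]
    shared <- Matrix::tcrossprod(sub)
    o <- (sum(shared > 0) - n) / 2  # off-diagonal intersecting pairs
    data.frame(group = g, n_proteins = n, expected = e, observed = o,
               excess = (o - e) / e)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(p_co = p_co, table = tab)
}
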