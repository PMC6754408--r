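# Permutation nulls. Two designs: sign flips that keep the experimental
# female/male pairing (confounders stay blocked) and group-size-preserving
# label shuffles. Resampling is without replacement throughout.

# Exhaustive enumeration kicks in automatically when the design space has at
# most this many assignments.
EXHAUSTIVE_LIMIT <- 2^14

#' Within-pair sign-flip assignments
#'
#' Each assignment swaps the female/male labels of every pair independently
#' with probability 1/2 (a sign vector over pairs). In exhaustive mode all
#' `2^n` assignments are returned, each exactly once.
#'
#' @param design A [build_pairing()] result (or anything with a `pairs` tibble).
#' @param B Number of Monte-Carlo assignments.
#' @param seed Integer seed.
#' @param exhaustive `TRUE`/`FALSE`, or `"auto"` (exhaustive when
#'   `2^n <= 16384`).
#' @return Integer matrix of +1/-1, one row per assignment, one column per
#'   pair. Attribute `exhaustive` records the mode.
#' @export
permute_within_pairs <- function(design, B = 1000, seed = 1L,
                                 exhaustive = FALSE) {
  n <- nrow(design$pairs)
  if (n < 1) stop("need at least one pair")
  if (identical(exhaustive, "auto")) exhaustive <- 2^n <= EXHAUSTIVE_LIMIT
  if (exhaustive) {
    if (2^n > EXHAUSTIVE_LIMIT) stop("design space too large to enumerate")
    grid <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    dimnames(grid) <- NULL
    return(structure(grid, exhaustive = TRUE))
  }
  with_seed(seed, {
    structure(matrix(sample(c(1L, -1L), B * n, replace = TRUE), nrow = B),
              exhaustive = FALSE)
  })
}

#' Group-label shuffle assignments
#'
#' Uniform random partitions of `n = sum(sizes)` items into two groups of the
#' given sizes; each row marks membership of group A. Exhaustive mode yields
#' every distinct partition exactly once.
#'
#' @param sizes Integer vector `c(n_A, n_B)`.
#' @param B Number of Monte-Carlo assignments.
#' @param seed Integer seed.
#' @param exhaustive `TRUE`/`FALSE` or `"auto"` (exhaustive when
#'   `choose(n, n_A) <= 16384`).
#' @return Logical matrix, one row per assignment, `TRUE` marking group A.
#' @export
permute_group_labels <- function(sizes, B = 1000, seed = 1L,
                                 exhaustive = FALSE) {
  stopifnot(length(sizes) == 2, all(sizes >= 1))
  n <- sum(sizes)
  n_comb <- choose(n, sizes[1])
  if (identical(exhaustive, "auto")) exhaustive <- n_comb <= EXHAUSTIVE_LIMIT
  if (exhaustive) {
    if (n_comb > EXHAUSTIVE_LIMIT) stop("design space too large to enumerate")
    combs <- utils::combn(n, sizes[1])
    out <- matrix(FALSE, ncol(combs), n)
    for (i in seq_len(ncol(combs))) out[i, combs[, i]] <- TRUE
    return(structure(out, exhaustive = TRUE))
  }
  with_seed(seed, {
    out <- matrix(FALSE, B, n)
    for (i in seq_len(B)) out[i, sample.int(n, sizes[1])] <- TRUE
    structure(out, exhaustive = FALSE)
  })
}

#' Permutation p-value for an arbitrary statistic
#'
#' Evaluates `statistic_fn(data, assignment)` under the chosen design's null
#' assignments and compares with the observed statistic (the identity
#' assignment). Monte-Carlo p-values use the add-one convention
#' `(1 + r) / (B + 1)` so p > 0 always; with exhaustive enumeration the p is
#' the exact fraction of assignments at least as extreme (the identity is one
#' of them). Two-sided tails compare `|statistic|`.
#'
#' @param statistic_fn Pure function of `(data, assignment)`. For the
#'   `within_pair_flip` design the assignment is a +1/-1 vector over pairs; for
#'   `group_label_shuffle` it is a logical vector marking group A.
#' @param data Passed through to `statistic_fn`.
#' @param design A [build_pairing()] result (sign-flip design) or a list
#'   `list(type = "labels", sizes = c(nA, nB))`.
#' @param B Number of Monte-Carlo permutations.
#' @param seed Integer seed.
#' @param tail `"two"` (on the absolute statistic), `"greater"` or `"less"`.
#' @param exhaustive `TRUE`/`FALSE`/`"auto"`.
#' @return A `perm_test`: list with `observed`, `null` (vector), `p`,
#'   `exceedances`, `B`, `design`, `tail`, `exhaustive`, `seed`.
#' @export
permutation_pvalue <- function(statistic_fn, data, design, B = 1000, seed = 1L,
                               tail = c("two", "greater", "less"),
                               exhaustive = "auto") {
  tail <- match.arg(tail)
  if (B < 1) stop("B must be >= 1")
  if (inherits(design, "paired_design")) {
    assignments <- permute_within_pairs(design, B = B, seed = seed,
                                        exhaustive = exhaustive)
    identity_assignment <- rep(1L, nrow(design$pairs))
    design_name <- "within_pair_flip"
  } else if (is.list(design) && identical(design$type, "labels")) {
    assignments <- permute_group_labels(design$sizes, B = B, seed = seed,
                                        exhaustive = exhaustive)
    identity_assignment <- c(rep(TRUE, design$sizes[1]), rep(FALSE, design$sizes[2]))
    design_name <- "group_label_shuffle"
  } else {
    stop("design must be a paired_design or list(type = 'labels', sizes = ...)")
  }
  was_exhaustive <- isTRUE(attr(assignments, "exhaustive"))
  observed <- statistic_fn(data, identity_assignment)
  null <- vapply(seq_len(nrow(assignments)),
                 function(i) statistic_fn(data, assignments[i, ]), numeric(1))
  score <- switch(tail, two = abs, greater = identity, less = function(x) -x)
  r <- sum(score(null) >= score(observed))
  p <- if (was_exhaustive) r / length(null) else (1 + r) / (length(null) + 1)
  structure(list(observed = observed, null = null, p = p, exceedances = r,
                 B = length(null), design = design_name, tail = tail,
                 exhaustive = was_exhaustive, seed = as.integer(seed)),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test> %s, observed = %.4g, p = %.4g (%d/%d %s, %s)\n",
              x$design, x$observed, x$p, x$exceedances, x$B,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo", x$tail))
  invisible(x)
}
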