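#' Specify a trail-choice decision rule
#'
#' Constructs the specification of the decision rule an individual forager
#' uses to pick one of several pheromone trails. Four rule families are
#' available, spanning the range from fully linear to extremely non-linear
#' responses to recruitment:
#'
#' * `"random"` — the null model: every trail is chosen with probability
#'   `1/s` and successful foragers lay no pheromone.
#' * `"linear"` — preference for a trail equals the proportion of the total
#'   pheromone it carries.
#' * `"sigmoidal"` — preference for trail \eqn{i} is
#'   \eqn{(k + c_i)^x / \sum_j (k + c_j)^x}, where \eqn{c_i} is the amount
#'   of pheromone on trail \eqn{i}. `k` is the intrinsic attractiveness of a
#'   trail regardless of pheromone (higher `k` flattens the response at low
#'   pheromone); `x` is the steepness of the non-linearity. `k = 0, x = 1`
#'   reduces exactly to the linear rule.
#' * `"ranked"` — foragers rank trails by strength and take the strongest
#'   with probability `p_top`; otherwise the same procedure is applied
#'   recursively to the remaining trails (`error_mode = "recursive"`, the
#'   default) or the remainder is split uniformly over the weaker trails
#'   (`error_mode = "uniform"`).
#'
#' @param variant One of `"random"`, `"linear"`, `"sigmoidal"`, `"ranked"`.
#' @param k Intrinsic trail attractiveness (sigmoidal only), `k >= 0`.
#' @param x Steepness exponent (sigmoidal only), `x > 0`.
#' @param p_top Probability of taking the strongest trail (ranked only),
#'   in `(0, 1]`. The default 0.75 corresponds to a 25% error rate.
#' @param error_mode How the ranked rule distributes the `1 - p_top` error
#'   mass: `"recursive"` (default) or `"uniform"`.
#'
#' @return An object of class `choice_rule`.
#' @examples
#' choice_rule("sigmoidal", k = 0, x = 2)
#' choice_rule("ranked", p_top = 0.75)
#' @export
choice_rule <- function(variant = c("linear", "sigmoidal", "ranked", "random"),
                        k = 0, x = 2, p_top = 0.75,
                        error_mode = c("recursive", "uniform")) {
  variant <- match.arg(variant)
  error_mode <- match.arg(error_mode)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop("`k` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop("`x` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p_top) || length(p_top) != 1L || is.na(p_top) ||
      p_top <= 0 || p_top > 1) {
    stop("`p_top` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(variant = variant, k = k, x = x, p_top = p_top,
         error_mode = error_mode),
    class = "choice_rule"
  )
}

#' @export
print.choice_rule <- function(x, ...) {
  lab <- switch(x$variant,
    random = "random (null model)",
    linear = "linear",
    sigmoidal = sprintf("sigmoidal (k = %g, x = %g)", x$k, x$x),
    ranked = sprintf("ranked (p_top = %g, %s errors)", x$p_top, x$error_mode)
  )
  cat("<choice_rule> ", lab, "\n", sep = "")
  invisible(x)
}

#' Short label for a choice rule, used in tables and plots
#' @param rule A [choice_rule()].
#' @return A character scalar such as `"sigmoidal k=0 x=2"`.
#' @export
rule_label <- function(rule) {
  stopifnot(inherits(rule, "choice_rule"))
  switch(rule$variant,
    random = "random",
    linear = "linear",
    sigmoidal = sprintf("sigmoidal k=%g x=%g", rule$k, rule$x),
    ranked = sprintf("ranked p=%g", rule$p_top)
  )
}

check_strengths <- function(strengths) {
  if (!is.numeric(strengths) || length(strengths) < 2L) {
    stop("pheromone strengths must be a numeric vector of length >= 2",
         call. = FALSE)
  }
  if (anyNA(strengths) || any(strengths < 0)) {
    stop("pheromone strengths must be non-negative and non-missing",
         call. = FALSE)
  }
  invisible(strengths)
}

#' Apply a discrimination threshold to trail strengths
#'
#' Ants may be unable to tell apart trails whose pheromone amounts differ by
#' less than some minimum detectable difference `d`. Trails are sorted by
#' strength and chained into groups wherever the gap between adjacent sorted
#' values is strictly less than `d` (single-linkage chaining, which turns the
#' non-transitive "indistinguishable" relation into a deterministic
#' partition). Every trail in a group is assigned the group's mean strength,
#' so downstream proportional rules treat them as equal and the ranked rule
#' treats them as tied.
#'
#' @param strengths Non-negative numeric vector of per-trail pheromone.
#' @param d Minimum detectable difference in pheromone units; `d = 0` means
#'   infinitely fine discrimination and returns the input unchanged.
#'
#' @return A list with `effective` (numeric vector of group-mean strengths,
#'   aligned with the input) and `groups` (list of integer vectors
#'   partitioning the trail indices).
#' @examples
#' apply_discrimination(c(1, 0.98, 0.5, 0.1), d = 0.05)
#' @export
apply_discrimination <- function(strengths, d) {
  check_strengths(strengths)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0) {
    stop("discrimination `d` must be a single non-negative number",
         call. = FALSE)
  }
  s <- length(strengths)
  ord <- order(strengths)
  sorted <- strengths[ord]
  # new group whenever the gap to the previous sorted value reaches d
  grp_sorted <- cumsum(c(1L, as.integer(!(diff(sorted) < d))))
  grp <- integer(s)
  grp[ord] <- grp_sorted
  means <- vapply(split(strengths, grp), mean, numeric(1))
  effective <- means[as.character(grp)]
  names(effective) <- NULL
  groups <- unname(split(seq_len(s), grp))
  # report groups from strongest to weakest
  groups <- groups[order(-vapply(groups, function(i) effective[i[1L]],
                                 numeric(1)))]
  list(effective = effective, groups = groups)
}

#' Preference probabilities over trails under a choice rule
#'
#' Computes the probability that a departing forager picks each trail, given
#' the current per-trail pheromone amounts. The discrimination threshold is
#' applied first ([apply_discrimination()]), then the rule-specific
#' computation. If every effective strength contributes zero weight (all
#' trails at zero pheromone under the linear rule, or `k = 0` with all-zero
#' trails under the sigmoidal rule) the choice falls back to uniform,
#' matching the behaviour of a colony before any recruitment.
#'
#' @param strengths Non-negative numeric vector of per-trail pheromone.
#' @param rule A [choice_rule()].
#' @param d Discrimination threshold, see [apply_discrimination()].
#'
#' @return Numeric probability vector aligned with `strengths`; entries are
#'   in `[0, 1]` and sum to 1.
#' @examples
#' preference(c(3, 1, 0, 0), choice_rule("linear"))
#' preference(c(3, 1, 0, 0), choice_rule("sigmoidal", k = 0, x = 2))
#' preference(c(1, 2, 3, 4), choice_rule("ranked"))
#' @export
preference <- function(strengths, rule, d = 0) {
  check_strengths(strengths)
  if (!inherits(rule, "choice_rule")) {
    stop("`rule` must be a choice_rule object", call. = FALSE)
  }
  s <- length(strengths)
  if (rule$variant == "random") {
    return(rep(1 / s, s))
  }
  disc <- apply_discrimination(strengths, d)
  eff <- disc$effective
  if (rule$variant == "ranked") {
    return(preference_ranked(eff, p_top = rule$p_top, groups = disc$groups,
                             error_mode = rule$error_mode))
  }
  k <- if (rule$variant == "linear") 0 else rule$k
  x <- if (rule$variant == "linear") 1 else rule$x
  w <- (k + eff)^x
  tot <- sum(w)
  if (tot <= 0) rep(1 / s, s) else w / tot
}

#' Preference probabilities under the ranked choice rule
#'
#' With strictly ranked trails the strongest is chosen with probability
#' `p_top`; with probability `1 - p_top` the same procedure recurses on the
#' remaining trails, the last remaining trail receiving the residual mass.
#' Trails tied in rank (either exactly equal strengths or members of the
#' same discrimination group) share the average of the positional masses
#' their block of ranks would receive, which equals averaging over all
#' strict orderings of the tied trails. With `error_mode = "uniform"` the
#' strongest still gets `p_top` but the error mass is split evenly over all
#' weaker trails.
#'
#' @param strengths Non-negative numeric vector of per-trail (effective)
#'   pheromone.
#' @param p_top Probability of taking the top-ranked trail, in `(0, 1]`.
#' @param groups Optional partition of trail indices (as returned by
#'   [apply_discrimination()]); members of one group are treated as tied.
#'   By default trails with exactly equal strengths are tied.
#' @param error_mode `"recursive"` (default) or `"uniform"`.
#'
#' @return Numeric probability vector aligned with `strengths`.
#' @examples
#' preference_ranked(c(4, 3, 2, 1), p_top = 0.75)
#' @export
preference_ranked <- function(strengths, p_top = 0.75, groups = NULL,
                              error_mode = c("recursive", "uniform")) {
  check_strengths(strengths)
  error_mode <- match.arg(error_mode)
  if (!is.numeric(p_top) || length(p_top) != 1L || is.na(p_top) ||
      p_top <= 0 || p_top > 1) {
    stop("`p_top` must be in (0, 1]", call. = FALSE)
  }
  s <- length(strengths)
  eff <- strengths
  if (!is.null(groups)) {
    if (length(unlist(groups)) != s ||
        !setequal(unlist(groups), seq_len(s))) {
      stop("`groups` must partition the trail indices", call. = FALSE)
    }
    for (g in groups) eff[g] <- mean(strengths[g])
  }
  # positional mass for each strict rank
  if (error_mode == "recursive") {
    q <- p_top * (1 - p_top)^(seq_len(s) - 1)
    q[s] <- (1 - p_top)^(s - 1)
  } else {
    q <- c(p_top, rep((1 - p_top) / (s - 1), s - 1))
  }
  ord <- order(-eff, seq_len(s))
  # average positional mass within blocks of tied (equal) strengths
  blocks <- cumsum(c(1L, as.integer(diff(eff[ord]) != 0)))
  q_avg <- stats::ave(q, blocks)
  prob <- numeric(s)
  prob[ord] <- q_avg
  prob
}

#' Sample a trail index from a preference vector
#'
#' @param prob Probability vector over trails (sums to 1).
#' @param n Number of independent draws.
#' @return Integer vector of trail indices in `1:length(prob)`.
#' @examples
#' set.seed(1)
#' sample_trail(c(0.75, 0.1875, 0.046875, 0.015625), n = 5)
#' @export
sample_trail <- function(prob, n = 1) {
  if (!is.numeric(prob) || anyNA(prob) || any(prob < 0) ||
      abs(sum(prob) - 1) > 1e-9) {
    stop("`prob` must be a probability vector summing to 1", call. = FALSE)
  }
  sample.int(length(prob), size = n, replace = TRUE, prob = prob)
}

# integer code used by the C++ engine
rule_code <- function(rule) {
  match(rule$variant, c("random", "linear", "sigmoidal", "ranked")) - 1L
}
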