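# Independent enumeration oracle for the recursive ranked rule: walk the
# decision tree over strict rankings explicitly, averaging over all
# permutations of tied trails. Kept deliberately naive (factorial cost) and
# structurally unrelated to preference_ranked().
ranked_oracle <- function(strengths, p_top) {
  s <- length(strengths)
  rec_masses <- function(m) {
    if (m == 1) return(1)
    c(p_top, (1 - p_top) * rec_masses(m - 1))
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v),
                  function(i) lapply(perms(v[-i]), function(p) c(v[i], p))),
           recursive = FALSE)
  }
  # all strict orderings consistent with the weak order of strengths
  ord_groups <- split(seq_len(s), -rank(strengths, ties.method = "min"))
  orderings <- Reduce(
    function(acc, g) {
      unlist(lapply(acc, function(a) {
        lapply(perms(g), function(p) c(a, p))
      }), recursive = FALSE)
    },
    ord_groups, accumulate = FALSE, init = list(integer(0))
  )
  q <- rec_masses(s)
  prob <- numeric(s)
  for (o in orderings) prob[o] <- prob[o] + q
  prob / length(orderings)
}

# tiny run for engine tests
quick_cfg <- function(colony = 50, n_steps = 200, ...) {
  sim_config(colony, n_steps = n_steps,
             analysis_window = max(1, n_steps - 100), ...)
}

# hand-built sweep-style table for the statistics layer
fake_table <- function(sizes, A_by_size, reps = 20, rule = "treatment") {
  dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
    tibble::tibble(
      rule = rule,
      colony_size = sizes[i],
      mean_active_foragers = sizes[i] * 0.296,
      A = A_by_size[[i]][((seq_len(reps) - 1) %% length(A_by_size[[i]])) + 1]
    )
  }))
}
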