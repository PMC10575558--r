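#' Translate strength triplets into an experiment design
#'
#' Scales selected strength triplets into motion coherences
#' (`coherence = strength * coherence_scale`, default 0.16) and resolves
#' coherence ties so that every condition has a well-defined highest,
#' second-highest and lowest stimulus: within each group of tied non-maximal
#' coherences, successive multiples of `tie_epsilon` are added to the
#' later-sorted members (so `[0, 0, 3.5]` becomes coherences
#' `[0, 0.0001, 0.56]`). The tie perturbation is applied in coherence space,
#' after scaling.
#'
#' @param strengths A list of length-3 strength triplets, a 3-column matrix,
#'   or a [select_conditions()] tibble.
#' @param coherence_scale Multiplier from strength units to coherence
#'   (must keep all coherences within \[0, 1\]).
#' @param tie_epsilon Coherence increment used to break ties.
#' @return An `experiment_design`: a tibble with one row per condition
#'   (`condition_id`, `label`, sorted strengths `c_lowest`, `c_second`,
#'   `c_highest`, and coherences `coh_lowest`, `coh_second`, `coh_highest`),
#'   with the scale and epsilon stored as attributes.
#' @export
#' @examples
#' design_from_strengths(list(c(0, 0, 3.5), c(3.5, 4.5, 5), c(4, 4.5, 5)))
design_from_strengths <- function(strengths, coherence_scale = 0.16,
                                  tie_epsilon = 1e-4) {
  m <- to_triplet_matrix(strengths)
  assert_scalar_number(coherence_scale, "coherence_scale", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(tie_epsilon, "tie_epsilon", lower = 0,
                       strict_lower = TRUE)
  if (coherence_scale * max(m) > 1) {
    abort("`coherence_scale` times the maximum strength exceeds 1.")
  }
  rows <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    cs <- sort(m[i, ]) # ascending: lowest, second, highest
    coh <- cs * coherence_scale
    coh <- break_coherence_ties(coh, tie_epsilon)
    if (any(coh > 1)) {
      abort(sprintf("Tie-broken coherences exceed 1 for condition [%s].",
                    paste(cs, collapse = ", ")))
    }
    tibble::tibble(
      condition_id = i,
      label = paste(cs, collapse = "_"),
      c_lowest = cs[1], c_second = cs[2], c_highest = cs[3],
      coh_lowest = coh[1], coh_second = coh[2], coh_highest = coh[3]
    )
  })
  if (any(rows$coh_second >= rows$coh_highest) ||
      any(rows$coh_lowest >= rows$coh_second)) {
    abort("Coherences are not strictly ordered after tie breaking.")
  }
  structure(rows, class = c("experiment_design", class(rows)),
            coherence_scale = coherence_scale, tie_epsilon = tie_epsilon)
}

# add 0, eps, 2*eps, ... within each group of tied values (ascending input)
break_coherence_ties <- function(coh, eps) {
  for (u in unique(coh)) {
    idx <- which(coh == u)
    if (length(idx) > 1L) {
      coh[idx] <- coh[idx] + eps * (seq_along(idx) - 1L)
    }
  }
  coh
}

#' The workflow's standard three-condition design
#'
#' Convenience constructor for the three utility-maximizing strength triplets
#' `[0, 0, 3.5]`, `[3.5, 4.5, 5]` and `[4, 4.5, 5]` that the condition
#' selection step identifies on the default grid, translated with the
#' standard 0.16 coherence scale and 0.0001 tie epsilon.
#'
#' @inheritParams design_from_strengths
#' @return An `experiment_design` with three conditions.
#' @export
#' @examples
#' default_design()
default_design <- function(coherence_scale = 0.16, tie_epsilon = 1e-4) {
  design_from_strengths(
    list(c(0, 0, 3.5), c(3.5, 4.5, 5), c(4, 4.5, 5)),
    coherence_scale = coherence_scale, tie_epsilon = tie_epsilon
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d conditions (scale %g, epsilon %g)\n",
              nrow(x), attr(x, "coherence_scale"), attr(x, "tie_epsilon")))
  print(tibble::as_tibble(unclass_design(x)))
  invisible(x)
}

unclass_design <- function(x) {
  class(x) <- setdiff(class(x), "experiment_design")
  x
}

# condition whose top-vs-second coherence gap is largest; used as the
# "easiest" condition in subject screening
easiest_condition <- function(design) {
  gaps <- design$coh_highest - design$coh_second
  design$condition_id[which.max(gaps)]
}

#' Map a chosen screen position to its choice category
#'
#' Each trial shows the condition's three coherences at screen positions
#' given by a random arrangement; the chosen position is categorized as
#' `"highest"` (the correct answer), `"second"` or `"lowest"` by the
#' condition's strict coherence ordering. Vectorized over trials.
#'
#' @param pos_highest,pos_second,pos_lowest Screen positions (1-3) holding
#'   the highest, second and lowest coherence.
#' @param choice_position The position the observer chose (1-3).
#' @return Character vector in `c("highest", "second", "lowest")`.
#' @export
#' @examples
#' categorize_choice(3, 1, 2, choice_position = 1) # "second"
categorize_choice <- function(pos_highest, pos_second, pos_lowest,
                              choice_position) {
  nn <- length(choice_position)
  ok <- pos_highest != pos_second & pos_highest != pos_lowest &
    pos_second != pos_lowest
  if (any(!ok)) abort("Arrangement positions must be a permutation of 1:3.")
  out <- rep(NA_character_, nn)
  out[choice_position == pos_highest] <- "highest"
  out[choice_position == pos_second] <- "second"
  out[choice_position == pos_lowest] <- "lowest"
  if (anyNA(out)) {
    abort("Some `choice_position` values match no arrangement position.")
  }
  out
}

choice_categories <- function() c("highest", "second", "lowest")
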