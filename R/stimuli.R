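#' Random odor code
#'
#' A unique odor is a binary pattern on a 6x4 grid (length-24 vector) with
#' exactly six cells on, drawn uniformly over the choose(24, 6) = 134,596
#' possible codes.
#'
#' @param field_size code length.
#' @param n_on number of active cells.
#' @return binary numeric vector of length `field_size`.
#' @export
make_odor <- function(field_size = 24, n_on = 6) {
  code <- numeric(field_size)
  code[sample.int(field_size, n_on)] <- 1
  code
}

new_problem <- function(a, b, rewarded, context = NA_character_) {
  stopifnot(rewarded %in% c(1L, 2L), a != b)
  list(a = a, b = b, rewarded = as.integer(rewarded), context = context)
}

#' Build the full stimulus set for one simulated rat
#'
#' Generates the odor vocabulary and the discrimination lists used across
#' the behavioral protocols:
#' \itemize{
#'   \item `list1`: problems `{X_i, Y_i}` with a randomly baited side, the
#'     set learned in context A.
#'   \item `list1_reversed`: the same pairs with the baited side flipped
#'     (the conflicting context-B list of the context-guided retrieval
#'     task).
#'   \item `pretrain_C`: `{X_i, Z_i}` (shares `X_i` with list 1) and
#'     `pretrain_D`: `{Z_i, Y_i}` (shares `Y_i`), the lifetime-experience
#'     lists learned in contexts C and D.
#'   \item `list2`: for each list-1 problem, one randomly chosen odor is
#'     retained, its partner is replaced by a novel odor `W_i`, and the
#'     retained odor's reward status is reversed (a previously rewarded
#'     retained odor becomes unrewarded and vice versa).
#'   \item `blocked`: `n_blocked` fresh `{X_i, Y_i}` problems for the
#'     one-at-a-time acquisition protocol.
#' }
#' Odor codes are sampled independently per label; uses the global RNG.
#'
#' @param n_problems problems per concurrent list.
#' @param n_blocked problems for the blocked-acquisition list.
#' @param field_size,n_on odor-code geometry.
#' @return A list of class `hippo_stimuli` with `codes` (named list of odor
#'   codes) and the problem lists above.
#' @export
make_experiment_stimuli <- function(n_problems = 8, n_blocked = 10,
                                    field_size = 24, n_on = 6) {
  n_lab <- max(n_problems, n_blocked)
  labels <- c(paste0("X", seq_len(n_lab)), paste0("Y", seq_len(n_lab)),
              paste0("Z", seq_len(n_problems)), paste0("W", seq_len(n_problems)))
  codes <- lapply(labels, function(l) make_odor(field_size, n_on))
  names(codes) <- labels

  baited <- sample(c(1L, 2L), n_problems, replace = TRUE)
  list1 <- lapply(seq_len(n_problems), function(i)
    new_problem(paste0("X", i), paste0("Y", i), baited[i]))
  list1_rev <- lapply(seq_len(n_problems), function(i)
    new_problem(paste0("X", i), paste0("Y", i), 3L - baited[i]))
  pretrain_C <- lapply(seq_len(n_problems), function(i)
    new_problem(paste0("X", i), paste0("Z", i),
                sample(c(1L, 2L), 1)))
  pretrain_D <- lapply(seq_len(n_problems), function(i)
    new_problem(paste0("Z", i), paste0("Y", i),
                sample(c(1L, 2L), 1)))

  retain <- sample(c(1L, 2L), n_problems, replace = TRUE)
  list2 <- lapply(seq_len(n_problems), function(i) {
    p1 <- list1[[i]]
    kept <- if (retain[i] == 1L) p1$a else p1$b
    novel <- paste0("W", i)
    kept_was_rewarded <- retain[i] == p1$rewarded
    # the retained odor's reward prediction is reversed
    if (kept_was_rewarded) new_problem(kept, novel, 2L)
    else                   new_problem(kept, novel, 1L)
  })

  blocked <- lapply(seq_len(n_blocked), function(i)
    new_problem(paste0("X", i), paste0("Y", i),
                sample(c(1L, 2L), 1)))

  structure(list(codes = codes, list1 = list1, list1_reversed = list1_rev,
                 pretrain_C = pretrain_C, pretrain_D = pretrain_D,
                 list2 = list2, blocked = blocked,
                 n_problems = n_problems, n_blocked = n_blocked),
            class = "hippo_stimuli")
}

#' Random presentation order for one block
#'
#' Each problem appears exactly once per block, in fresh random order.
#'
#' @param problems a problem list.
#' @return integer permutation of `seq_along(problems)`.
#' @export
block_order <- function(problems) {
  sample.int(length(problems))
}

#' Export / import a stimulus set as JSON
#'
#' @param stim a `hippo_stimuli` object.
#' @param path file path.
#' @return `stimuli_to_json` returns `path` invisibly; `stimuli_from_json`
#'   returns the restored `hippo_stimuli`.
#' @export
stimuli_to_json <- function(stim, path) {
  jsonlite::write_json(unclass(stim), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname stimuli_to_json
#' @export
stimuli_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_list <- function(df) {
    if (is.null(df)) return(NULL)
    lapply(seq_len(nrow(df)), function(i)
      new_problem(df$a[i], df$b[i], df$rewarded[i], df$context[i]))
  }
  structure(list(codes = lapply(raw$codes, as.numeric),
                 list1 = fix_list(raw$list1),
                 list1_reversed = fix_list(raw$list1_reversed),
                 pretrain_C = fix_list(raw$pretrain_C),
                 pretrain_D = fix_list(raw$pretrain_D),
                 list2 = fix_list(raw$list2),
                 blocked = fix_list(raw$blocked),
                 n_problems = raw$n_problems, n_blocked = raw$n_blocked),
            class = "hippo_stimuli")
}
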