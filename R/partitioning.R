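# Variation partitioning: inclusion-exclusion on cross-validated scores of
# partial and joint models, for two or three explanation sets. Under
# cross-validation individual partitions may be negative ("paradoxical");
# they are reported as-is with a flag.

#' Two-way partition of explained variation
#'
#' From scores of the two partial models and the joint model (computed on
#' identical rows and fold assignments):
#' unique `A* = AB - B`, `B* = AB - A`; intersection `A:B = A + B - AB`.
#'
#' @param score_A,score_B,score_AB cross-validated scores.
#' @param labels length-2 character vector naming the sets.
#' @return object of class `readobs_partition`: data.frame `partitions`
#'   (partition, value, paradoxical), plus `joint`.
#' @export
partition_two <- function(score_A, score_B, score_AB,
                          labels = c("A", "B")) {
  vals <- c(score_AB - score_B, score_AB - score_A,
            score_A + score_B - score_AB)
  parts <- data.frame(
    partition = c(paste0(labels, "*"),
                  paste(labels[1], labels[2], sep = ":")),
    value = vals, paradoxical = vals < 0, stringsAsFactors = FALSE)
  structure(list(partitions = parts, joint = score_AB, n_sets = 2L,
                 labels = labels),
            class = "readobs_partition")
}

#' Three-way partition of explained variation
#'
#' Takes the seven scores `A, B, C, AB, AC, BC, ABC` (identical rows and
#' folds) and returns the seven partitions: the triple overlap
#' `A:B:C = ABC + A + B + C - AB - AC - BC`, the pairwise overlaps
#' excluding the third set, e.g. `A:B\\C = A + B - AB - A:B:C`, and the
#' uniques, e.g. `A* = ABC - BC`. The seven partitions sum to the joint
#' score exactly (algebraic identity).
#'
#' @param scores named numeric vector with elements
#'   `A, B, C, AB, AC, BC, ABC`, e.g. from [score_model_combinations()].
#' @param labels length-3 character vector naming the sets (defaults to
#'   the `labels` attribute of `scores` if present).
#' @return object of class `readobs_partition` (see [partition_two()]).
#' @export
partition_three <- function(scores, labels = NULL) {
  need <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  if (!all(need %in% names(scores)))
    stop_readobs(paste("scores must be named", paste(need, collapse = ", ")),
                 "readobs_bad_scores")
  labels <- labels %||% attr(scores, "labels") %||% c("A", "B", "C")
  s <- as.list(scores[need])
  abc <- s$ABC + s$A + s$B + s$C - s$AB - s$AC - s$BC
  vals <- c(
    s$ABC - s$BC,                 # A*
    s$ABC - s$AC,                 # B*
    s$ABC - s$AB,                 # C*
    s$A + s$B - s$AB - abc,       # A:B \ C
    s$A + s$C - s$AC - abc,       # A:C \ B
    s$B + s$C - s$BC - abc,       # B:C \ A
    abc)                          # A:B:C
  nm <- c(paste0(labels, "*"),
          paste0(labels[1], ":", labels[2], "\\", labels[3]),
          paste0(labels[1], ":", labels[3], "\\", labels[2]),
          paste0(labels[2], ":", labels[3], "\\", labels[1]),
          paste(labels, collapse = ":"))
  parts <- data.frame(partition = nm, value = vals, paradoxical = vals < 0,
                      stringsAsFactors = FALSE)
  structure(list(partitions = parts, joint = unname(scores["ABC"]),
                 n_sets = 3L, labels = labels),
            class = "readobs_partition")
}

#' @export
print.readobs_partition <- function(x, ...) {
  cat(sprintf("<readobs_partition> %d sets, joint score %.4f\n",
              x$n_sets, x$joint))
  print(x$partitions, row.names = FALSE)
  invisible(x)
}
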