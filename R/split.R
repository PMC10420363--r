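#' Partition a dataset into training, validation and test sets
#'
#' Subjects -- never individual trials -- are randomly assigned to the three
#' partitions so that a person's data appears in exactly one of them
#' (patient-level stratification). Assignment is done independently within
#' each pathology class with largest-remainder rounding of subject counts,
#' so small classes still honour the requested proportions as closely as
#' integer counts allow. Classes listed in `holdout_classes` are placed
#' entirely in the test set, supporting zero-shot evaluation of a pathology
#' never seen in training (the drop-foot protocol).
#'
#' @param dataset a `gait_dataset`.
#' @param fractions numeric length-3 `(train, val, test)` summing to 1;
#'   default `c(0.6, 0.1, 0.3)`.
#' @param holdout_classes character vector of pathology labels sent wholly
#'   to TEST.
#' @param seed integer; the assignment is deterministic given the seed.
#' @return The dataset with its `partition` filled in.
#' @examples
#' ds <- simulate_cohort(cohort_spec(list(
#'   list(profile = gait_profile("HC-heel"), n_subjects = 5, trials_per_subject = 1)),
#'   seed = 1))
#' ds <- split_dataset(ds, seed = 7)
#' table(ds$partition)
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.1, 0.3),
                          holdout_classes = character(), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1)) {
    stop_fmt("fractions must be three values in (0,1)")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop_fmt("fractions must sum to 1")

  subj <- vapply(dataset$trials, function(t) t$subject_id, "")
  path <- vapply(dataset$trials, function(t) t$pathology, "")
  subj_path <- tapply(path, subj, function(p) p[1L])

  assign_part <- character(0)
  parts <- c("TRAIN", "VAL", "TEST")
  for (cls in sort(unique(subj_path))) {
    members <- sort(names(subj_path)[subj_path == cls])
    n <- length(members)
    if (cls %in% holdout_classes) {
      assign_part[members] <- "TEST"
      next
    }
    if (n < 3L) {
      stop_fmt(paste0("pathology class %s has only %d subject(s); ",
                      "cannot fill all partitions - consider holdout_classes"), cls, n)
    }
    quota <- largest_remainder(n, fractions)
    perm <- with_seed(derive_seed(seed, "split", cls), sample(members))
    assign_part[perm] <- rep(parts, times = quota)
  }

  ids <- names(dataset$trials)
  partition <- assign_part[subj]
  names(partition) <- ids
  dataset$partition <- partition
  validate_dataset(dataset)
  dataset
}

## Integer apportionment of n into round(n * fractions) by largest remainder.
largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
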