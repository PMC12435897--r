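#' Down-sample to balanced classes and split into train/test
#'
#' The majority class is down-sampled uniformly at random to the minority
#' count, then each class is split with \code{floor(fraction * class_size)}
#' sequences in training and the remainder in test. The partition is fully
#' reproducible from the seed. With 421 sequences per class at fraction
#' 0.8 this yields 672 training and 170 test sequences; with 226 per
#' class, 360 and 92.
#'
#' @param tags named character vector of class labels (\code{"CC"} /
#'   \code{"CXC"}); names are sequence ids.
#' @param fraction training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return list with \code{train}, \code{test} (character id vectors),
#'   \code{per_class} (balanced class size) and \code{seed}.
#' @export
downsample_and_split <- function(tags, fraction = 0.8, seed = 1L) {
  stopifnot(!is.null(names(tags)))
  classes <- sort(unique(tags))
  if (length(classes) != 2L) stop("exactly two classes required")
  sizes <- table(tags)
  if (any(sizes < 2L)) stop("each class needs at least 2 sequences")
  m <- min(sizes)
  n_train <- floor(fraction * m)
  if (n_train < 1L || n_train >= m) {
    stop("degenerate split: fraction ", fraction, " at class size ", m,
         " leaves an empty train or test set")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train <- character(0)
  test <- character(0)
  for (cl in classes) {
    ids <- names(tags)[tags == cl]
    ids <- if (length(ids) > m) sample(ids, m) else ids
    tr <- sample(ids, n_train)
    train <- c(train, tr)
    test <- c(test, setdiff(ids, tr))
  }
  list(train = train, test = test, per_class = as.integer(m),
       seed = as.integer(seed))
}

#' Ensure the training split covers every residue seen in test
#'
#' Position-specific classification requires the model to have seen every
#' residue symbol that appears in the test set. If any residue at the
#' position occurs in test but not in training, the seed is advanced
#' deterministically (seed + 1, retry) until coverage holds or the attempt
#' budget exhausts. The adjustment is blind to classification accuracy.
#'
#' @param column named character vector of residues at the position
#'   (names = sequence ids; may contain gaps, which count as a symbol).
#' @param tags class labels as in [downsample_and_split()].
#' @param fraction,seed as in [downsample_and_split()].
#' @param max_attempts retry budget (default 100).
#' @return the covering partition with an extra \code{seed_used} element,
#'   or NULL when no covering partition was found within the budget (the
#'   position is then flagged uncoverable by callers and excluded).
#' @export
ensure_residue_coverage <- function(column, tags, fraction = 0.8,
                                    seed = 1L, max_attempts = 100L) {
  stopifnot(!is.null(names(column)))
  for (s in seq(seed, seed + max_attempts - 1L)) {
    part <- downsample_and_split(tags, fraction, s)
    tr <- unique(column[part$train])
    te <- unique(column[part$test])
    if (all(te %in% tr)) {
      part$seed_used <- as.integer(s)
      return(part)
    }
  }
  NULL
}

# Ridge-stabilised logistic regression on a single categorical column.
# With one indicator per symbol the coefficients decouple, so each is the
# 1-D Newton solution of  max  n1*log p + n0*log(1-p) - lambda/2 * beta^2
# with p = plogis(beta).  Returns P(class1 | symbol) per training symbol.
fit_symbol_logistic <- function(symbols, is_class1, lambda = 1e-4) {
  probs <- vapply(unique(symbols), function(s) {
    n1 <- sum(is_class1[symbols == s])
    n0 <- sum(!is_class1[symbols == s])
    beta <- 0
    for (it in 1:100) {
      p <- stats::plogis(beta)
      grad <- n1 * (1 - p) - n0 * p - lambda * beta
      hess <- -(n1 + n0) * p * (1 - p) - lambda
      step <- grad / hess
      beta <- beta - step
      if (abs(step) < 1e-10) break
    }
    stats::plogis(beta)
  }, 0)
  names(probs) <- unique(symbols)
  probs
}

#' Per-position subfamily scores (CC versus CXC logistic regression)
#'
#' For each labeled position, the single column is encoded categorically
#' (one indicator per observed symbol, the gap as its own symbol), a
#' two-class logistic regression is fitted on a balanced, coverage-checked
#' training split and scored for accuracy on the held-out test split, and
#' accuracies are averaged over replicate partitions. Positions with mean
#' accuracy at or above the threshold are flagged subfamily-predictive.
#' Class orientation: CXC is class 1. Predicted class is CXC iff the
#' fitted probability exceeds 0.5; a probability of exactly 0.5 resolves
#' to CC for determinism.
#'
#' @param aln a \code{labeled_alignment}; only CC and CXC records are
#'   used (others are dropped).
#' @param positions character vector of position labels to score (default:
#'   all labeled columns).
#' @param n_replicates number of replicate partitions (default 3).
#' @param seeds integer seeds, one per replicate (default 1:n_replicates).
#' @param fraction training fraction (default 0.8).
#' @param threshold subfamily-predictive flag threshold on the mean
#'   accuracy (default 0.75).
#' @param lambda ridge stabiliser of the logistic fit.
#' @return data.frame with \code{label}, \code{mean_accuracy}, \code{sd},
#'   \code{n_replicates_ok}, \code{predictive}, \code{flag}
#'   (\code{""}, \code{"degenerate"} or \code{"uncoverable"}); attributes
#'   record class sizes, split sizes and seeds.
#' @export
subfamily_scores <- function(aln, positions = NULL, n_replicates = 3L,
                             seeds = NULL, fraction = 0.8,
                             threshold = 0.75, lambda = 1e-4) {
  if (is.null(seeds)) seeds <- seq_len(n_replicates)
  stopifnot(length(seeds) == n_replicates)
  keep <- aln$records$subfamily %in% c("CC", "CXC")
  if (!any(keep)) stop("no CC/CXC sequences in alignment")
  tags <- stats::setNames(aln$records$subfamily[keep],
                          aln$records$seq_id[keep])
  m <- aln_matrix(aln)[names(tags), , drop = FALSE]
  if (is.null(positions)) positions <- aln$labels[!is.na(aln$labels)]
  cols <- match(positions, aln$labels)
  if (anyNA(cols)) {
    stop("unknown position label(s): ",
         paste(positions[is.na(cols)], collapse = ", "))
  }
  res <- lapply(seq_along(cols), function(k) {
    column <- stats::setNames(m[, cols[k]], names(tags))
    accs <- rep(NA_real_, n_replicates)
    flag <- ""
    if (length(unique(column)) == 1L) flag <- "degenerate"
    for (r in seq_len(n_replicates)) {
      part <- ensure_residue_coverage(column, tags, fraction, seeds[r])
      if (is.null(part)) {
        flag <- "uncoverable"
        next
      }
      probs <- fit_symbol_logistic(column[part$train],
                                   tags[part$train] == "CXC", lambda)
      p_test <- probs[column[part$test]]
      pred <- ifelse(p_test > 0.5, "CXC", "CC")
      accs[r] <- mean(pred == tags[part$test])
    }
    ok <- !is.na(accs)
    data.frame(label = positions[k],
               mean_accuracy = if (any(ok)) mean(accs[ok]) else NA_real_,
               sd = if (sum(ok) > 1L) stats::sd(accs[ok]) else NA_real_,
               n_replicates_ok = sum(ok), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$predictive <- !is.na(out$mean_accuracy) &
    out$mean_accuracy >= threshold
  per_class <- min(table(tags))
  attr(out, "per_class") <- as.integer(per_class)
  attr(out, "n_train") <- 2L * floor(fraction * per_class)
  attr(out, "n_test") <- 2L * (per_class - floor(fraction * per_class))
  attr(out, "seeds") <- as.integer(seeds)
  attr(out, "threshold") <- threshold
  out
}

#' Per-position prediction probabilities for a query sequence
#'
#' Trains the same position-specific models as [subfamily_scores()] and
#' evaluates the query's residue at each position, returning the mean
#' class-1 (CXC) probability across replicates. A score near 0 says the
#' position looks CC-like with high confidence; near 1, CXC-like. Query
#' residues unseen in training at a position are flagged undefined, not
#' imputed.
#'
#' @param query named character vector: the query's residues aligned to
#'   the family columns (names are position labels), or a
#'   single aligned string of the alignment's width.
#' @inheritParams subfamily_scores
#' @param query_id identifier recorded in the output.
#' @return data.frame with \code{label}, \code{probability},
#'   \code{n_replicates_ok} and \code{flag} (\code{""} or
#'   \code{"unseen"}).
#' @export
prediction_probabilities <- function(query, aln, positions = NULL,
                                     n_replicates = 3L, seeds = NULL,
                                     fraction = 0.8, lambda = 1e-4,
                                     query_id = "query") {
  if (is.null(seeds)) seeds <- seq_len(n_replicates)
  stopifnot(length(seeds) == n_replicates)
  if (length(query) == 1L && is.null(names(query))) {
    stopifnot(nchar(query) == aln_width(aln))
    chars <- strsplit(query, "")[[1]]
    keep <- !is.na(aln$labels)
    query <- stats::setNames(chars[keep], aln$labels[keep])
  }
  keep <- aln$records$subfamily %in% c("CC", "CXC")
  tags <- stats::setNames(aln$records$subfamily[keep],
                          aln$records$seq_id[keep])
  m <- aln_matrix(aln)[names(tags), , drop = FALSE]
  if (is.null(positions)) positions <- intersect(
    aln$labels[!is.na(aln$labels)], names(query))
  cols <- match(positions, aln$labels)
  res <- lapply(seq_along(cols), function(k) {
    column <- stats::setNames(m[, cols[k]], names(tags))
    q <- query[[positions[k]]]
    ps <- rep(NA_real_, n_replicates)
    flag <- ""
    for (r in seq_len(n_replicates)) {
      part <- ensure_residue_coverage(column, tags, fraction, seeds[r])
      if (is.null(part)) next
      probs <- fit_symbol_logistic(column[part$train],
                                   tags[part$train] == "CXC", lambda)
      if (!q %in% names(probs)) {
        flag <- "unseen"
        next
      }
      ps[r] <- probs[[q]]
    }
    ok <- !is.na(ps)
    data.frame(label = positions[k],
               probability = if (any(ok)) mean(ps[ok]) else NA_real_,
               n_replicates_ok = sum(ok), flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "query_id") <- query_id
  attr(out, "seeds") <- as.integer(seeds)
  out
}

#' Classify the CC/CXC character of a query's interface
#'
#' Among the query positions that make intermolecular contacts and are
#' subfamily-predictive (score at or above the threshold), counts how many
#' look CXC-like (prediction probability > 0.5) versus CC-like (< 0.5).
#' Probabilities of exactly 0.5 are counted in neither bucket and reported
#' separately.
#'
#' @param prob_profile result of [prediction_probabilities()].
#' @param contact_labels character vector of position labels making
#'   contacts.
#' @param score_profile result of [subfamily_scores()] (or any data.frame
#'   with \code{label} and \code{mean_accuracy}).
#' @param threshold subfamily-score qualification threshold (default 0.75).
#' @return list with \code{pct_cc}, \code{pct_cxc}, \code{n_qualifying},
#'   \code{n_tied}.
#' @export
classify_interface_character <- function(prob_profile, contact_labels,
                                         score_profile, threshold = 0.75) {
  sc <- stats::setNames(score_profile$mean_accuracy, score_profile$label)
  q <- prob_profile[prob_profile$label %in% contact_labels &
                      !is.na(prob_profile$probability), , drop = FALSE]
  q <- q[!is.na(sc[q$label]) & sc[q$label] >= threshold, , drop = FALSE]
  n_tied <- sum(q$probability == 0.5)
  n <- nrow(q) - n_tied
  if (n < 1L) {
    warning("no qualifying contact positions")
    return(list(pct_cc = NA_real_, pct_cxc = NA_real_,
                n_qualifying = 0L, n_tied = n_tied))
  }
  n_cxc <- sum(q$probability > 0.5)
  list(pct_cc = 100 * (n - n_cxc) / n, pct_cxc = 100 * n_cxc / n,
       n_qualifying = as.integer(n), n_tied = as.integer(n_tied))
}
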