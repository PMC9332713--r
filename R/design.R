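# Cross-validation fold construction for the two train/test separation
# scenarios, plus balanced impostor sampling. Feature vectors are
# referenced by provenance rows (subject_id, session_id, segment_index);
# a split plan never stores feature values.

new_split_plan <- function(scenario, subject, fold, genuine_train,
                           genuine_test, impostor_train, impostor_test,
                           seed) {
  plan <- list(scenario = scenario, verified_subject = subject,
               fold_index = fold,
               genuine_train = genuine_train, genuine_test = genuine_test,
               impostor_train = impostor_train, impostor_test = impostor_test,
               seed = seed)
  class(plan) <- "split_plan"
  validate_split_plan(plan)
  plan
}

validate_split_plan <- function(plan) {
  key <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    prov_key(df$subject_id, df$session_id, df$segment_index)
  }
  gtr <- key(plan$genuine_train); gte <- key(plan$genuine_test)
  itr <- key(plan$impostor_train); ite <- key(plan$impostor_test)
  if (length(intersect(gtr, gte)) > 0) {
    stop("split plan leaks genuine vectors between train and test")
  }
  if (length(intersect(itr, ite)) > 0) {
    stop("split plan leaks impostor vectors between train and test")
  }
  imp <- rbind(plan$impostor_train, plan$impostor_test)
  if (nrow(imp) > 0 && any(imp$subject_id == plan$verified_subject)) {
    stop("impostor lists contain the verified subject")
  }
  if (nrow(plan$impostor_train) != nrow(plan$genuine_train)) {
    stop("impostor training set must balance the genuine training set")
  }
  if (plan$scenario == 2) {
    if (length(intersect(plan$genuine_train$session_id,
                         plan$genuine_test$session_id)) > 0) {
      stop("scenario 2 requires session-disjoint genuine train/test sets")
    }
  }
  invisible(plan)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> scenario %d, subject %s, fold %d: genuine %d/%d, impostor %d/%d (train/test)\n",
    x$scenario, x$verified_subject, x$fold_index,
    nrow(x$genuine_train), nrow(x$genuine_test),
    nrow(x$impostor_train), nrow(x$impostor_test)))
  invisible(x)
}

#' Within-session cross-validation folds (scenario 1)
#'
#' Builds the four folds of the first scenario, in which training and
#' testing vectors come from different parts of the *same* sessions.
#' Within each session the 24 segment vectors are shuffled (seeded) and
#' split into 4 clusters of 6; fold k tests cluster k of every session
#' and trains on the other three clusters. Every genuine vector is
#' tested in exactly one fold. Impostor vectors are drawn fresh per fold
#' from `impostor_pool`, balancing the genuine counts.
#'
#' @param genuine_prov provenance data.frame (`subject_id`,
#'   `session_id`, `segment_index`) of all vectors of the verified
#'   subject; every session must contribute the same vector count,
#'   divisible by `n_clusters`.
#' @param impostor_pool provenance data.frame of the other genuine
#'   subjects' vectors (must exclude the verified subject).
#' @param seed integer seed controlling the shuffles and impostor draws.
#' @param n_clusters number of clusters per session (= number of folds).
#' @param pool_sessions if `TRUE`, shuffle all of the subject's vectors
#'   pooled across sessions before clustering, instead of clustering
#'   within each session (the default). Both readings keep train and
#'   test inside the same sessions; the per-session one guarantees every
#'   session contributes equally to every fold.
#' @return List of `n_clusters` `split_plan` objects.
#' @export
scenario1_folds <- function(genuine_prov, impostor_pool, seed,
                            n_clusters = 4, pool_sessions = FALSE) {
  subject <- unique(genuine_prov$subject_id)
  if (length(subject) != 1) stop("genuine_prov must hold a single subject")
  sessions <- sort(unique(genuine_prov$session_id))
  per_sess <- table(genuine_prov$session_id)
  if (length(unique(per_sess)) != 1) {
    stop("all sessions must contribute the same number of vectors")
  }
  nv <- unname(per_sess[1])
  if (nv %% n_clusters != 0) {
    stop(sprintf("vectors per session (%d) not divisible by %d clusters",
                 nv, n_clusters))
  }
  csize <- nv / n_clusters

  cluster_of <- integer(nrow(genuine_prov))
  if (pool_sessions) {
    # pooled reading: one shuffle over all vectors, 4 equal clusters
    perm <- with_seed(derive_seed(seed, "s1shuffle", subject, "pooled"),
                      sample(nrow(genuine_prov)))
    cluster_of[perm] <- rep(seq_len(n_clusters),
                            each = nrow(genuine_prov) / n_clusters)
  } else {
    # seeded per-session shuffle, then consecutive blocks of csize
    for (s in sessions) {
      idx <- which(genuine_prov$session_id == s)
      perm <- with_seed(derive_seed(seed, "s1shuffle", subject, s),
                        sample(length(idx)))
      cluster_of[idx[perm]] <- rep(seq_len(n_clusters), each = csize)
    }
  }

  lapply(seq_len(n_clusters), function(k) {
    test_idx <- cluster_of == k
    gte <- genuine_prov[test_idx, , drop = FALSE]
    gtr <- genuine_prov[!test_idx, , drop = FALSE]
    imp <- sample_impostors(impostor_pool, nrow(gtr), nrow(gte),
                            derive_seed(seed, "s1imp", subject, k),
                            verified_subject = subject)
    new_split_plan(1L, subject, k - 1L, gtr, gte,
                   imp$impostor_train, imp$impostor_test, seed)
  })
}

#' Session-disjoint cross-validation folds (scenario 2)
#'
#' Builds the four folds of the second scenario, in which training and
#' testing vectors come from chronologically different sessions: the
#' first `train_fraction` of the subject's sessions (by session index)
#' train, the remaining sessions test. With the study default of 20
#' sessions and `train_fraction = 0.75` this is the first 15 sessions
#' for training and the last 5 for testing. The genuine sets are
#' identical across the four folds; only the impostor draws differ.
#'
#' @inheritParams scenario1_folds
#' @param n_folds number of impostor re-draws (default 4).
#' @param train_fraction fraction of sessions assigned to training.
#' @return List of `n_folds` `split_plan` objects.
#' @export
scenario2_folds <- function(genuine_prov, impostor_pool, seed,
                            n_folds = 4, train_fraction = 0.75) {
  subject <- unique(genuine_prov$subject_id)
  if (length(subject) != 1) stop("genuine_prov must hold a single subject")
  sessions <- sort(unique(genuine_prov$session_id))
  if (length(sessions) < 2) stop("scenario 2 needs at least 2 sessions")
  n_train_sess <- floor(length(sessions) * train_fraction)
  if (n_train_sess < 1 || n_train_sess >= length(sessions)) {
    stop("train_fraction leaves no sessions for training or testing")
  }
  train_sessions <- sessions[seq_len(n_train_sess)]
  gtr <- genuine_prov[genuine_prov$session_id %in% train_sessions, ,
                      drop = FALSE]
  gte <- genuine_prov[!genuine_prov$session_id %in% train_sessions, ,
                      drop = FALSE]
  lapply(seq_len(n_folds), function(k) {
    imp <- sample_impostors(impostor_pool, nrow(gtr), nrow(gte),
                            derive_seed(seed, "s2imp", subject, k),
                            verified_subject = subject)
    new_split_plan(2L, subject, k - 1L, gtr, gte,
                   imp$impostor_train, imp$impostor_test, seed)
  })
}

#' Balanced impostor draw
#'
#' Draws `n_train + n_test` impostor vector references uniformly without
#' replacement from the pool of the other genuine subjects' vectors, so
#' that positive and negative cases are balanced in training; the train
#' and test draws are disjoint by construction.
#'
#' @param pool provenance data.frame of candidate impostor vectors.
#' @param n_train,n_test draw sizes.
#' @param seed integer seed.
#' @param verified_subject subject that must not appear in the pool.
#' @return List with `impostor_train` and `impostor_test` provenance
#'   data.frames.
#' @export
sample_impostors <- function(pool, n_train, n_test, seed,
                             verified_subject = NULL) {
  if (!is.null(verified_subject) &&
      any(pool$subject_id == verified_subject)) {
    stop("impostor pool contains the verified subject")
  }
  need <- n_train + n_test
  if (nrow(pool) < need) {
    stop(sprintf("impostor pool exhausted: need %d, have %d", need,
                 nrow(pool)))
  }
  idx <- with_seed(seed, sample(nrow(pool), need))
  list(impostor_train = pool[idx[seq_len(n_train)], , drop = FALSE],
       impostor_test = pool[idx[n_train + seq_len(n_test)], , drop = FALSE])
}

#' Serialize split plans to JSON
#'
#' Writes plans as lists of (subject, session, segment) triples plus
#' seeds, sufficient to replay any run exactly.
#'
#' @param plans list of `split_plan` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_split_plans_json <- function(plans, path) {
  ser <- lapply(plans, function(p) {
    p[c("scenario", "verified_subject", "fold_index", "genuine_train",
        "genuine_test", "impostor_train", "impostor_test", "seed")]
  })
  jsonlite::write_json(ser, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
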