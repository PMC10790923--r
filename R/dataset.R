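# Labelled dataset construction: pain/no-pain duration matching, SMOTE
# minority oversampling, and assembly of the three classification tasks.

#' Match a no-pain session's duration to its pain counterpart
#'
#' The pain condition only provides usable data while the foot is immersed,
#' so the no-pain game of the same participant and demand level is truncated
#' to the first T seconds of its game interval, where T is the pain session's
#' immersion duration. If the immersion outlasts the no-pain game (it cannot
#' under the shared 180-s cap, but defensively), the no-pain length is kept
#' with a warning.
#'
#' @param pain_session,nopain_session \code{hemodynamic_series} (or any
#'   object carrying an \code{events} table) for the same participant and
#'   demand level.
#' @return List with \code{duration_s} (the matched duration from game
#'   start) -- feed it to [assemble_features()] as \code{max_duration_s} --
#'   and the two session labels.
#' @export
match_durations <- function(pain_session, nopain_session) {
  if (!identical(pain_session$participant_id, nopain_session$participant_id))
    stop("duration matching requires sessions from the same participant")
  pd <- session_labels(pain_session$condition)$demand
  nd <- session_labels(nopain_session$condition)$demand
  if (!identical(pd, nd))
    stop("duration matching requires sessions at the same demand level")
  imm <- event_interval(pain_session, "immersion")
  if (is.null(imm)) stop("pain session has no immersion event")
  game_p <- event_interval(pain_session, "game")
  game_n <- event_interval(nopain_session, "game")
  if (is.null(game_n)) stop("no-pain session has no game event")
  dur <- imm[2] - imm[1]
  nopain_len <- game_n[2] - game_n[1]
  if (dur > nopain_len + 1e-9) {
    warning("immersion (", round(dur, 1), " s) outlasts the no-pain game (",
            round(nopain_len, 1), " s); clipping to the game length")
    dur <- nopain_len
  }
  list(duration_s = dur, participant_id = pain_session$participant_id,
       demand = pd)
}

#' Synthetic minority over-sampling (SMOTE)
#'
#' Each synthetic point is drawn on the segment between a minority sample and
#' one of its \code{k_neighbors} nearest minority neighbours (Euclidean), at
#' a uniform random gap in (0, 1); base points are cycled in random order
#' until the minority count reaches \code{target_count}. Synthetic points
#' therefore never leave the convex hull of the minority class.
#'
#' @param x_minority Numeric matrix of minority-class rows (>= 2 rows).
#' @param target_count Desired total minority count (typically the majority
#'   count). No points are generated if already reached.
#' @param k_neighbors Neighbourhood size. Default 5, shrunk to
#'   \code{nrow - 1} when the minority class is smaller.
#' @param seed Optional seed for reproducible gaps/neighbour picks.
#' @return Matrix of \code{target_count} rows: the original minority rows
#'   followed by the synthetic rows.
#' @export
smote <- function(x_minority, target_count, k_neighbors = 5, seed = NULL) {
  x_minority <- as.matrix(x_minority)
  n <- nrow(x_minority)
  if (n < 2) stop("SMOTE needs at least 2 minority samples")
  k <- min(k_neighbors, n - 1L)
  n_new <- target_count - n
  if (n_new <= 0) return(x_minority[seq_len(max(target_count, 0)), ,
                                    drop = FALSE])
  gen <- function() {
    d <- as.matrix(stats::dist(x_minority))
    diag(d) <- Inf
    nn <- matrix(vapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)],
                        integer(k)), nrow = k)
    base <- rep(sample(n), length.out = n_new)
    synth <- matrix(0, n_new, ncol(x_minority))
    for (i in seq_len(n_new)) {
      b <- base[i]
      nb <- nn[sample(k, 1), b]
      gap <- stats::runif(1)
      synth[i, ] <- x_minority[b, ] + gap * (x_minority[nb, ] -
                                               x_minority[b, ])
    }
    synth
  }
  synth <- if (is.null(seed)) gen() else with_seed(seed, gen())
  out <- rbind(x_minority, synth)
  rownames(out) <- NULL
  out
}

#' Build a labelled dataset for one classification task
#'
#' Three tasks: \code{"demand"} (Easy vs Hard over the full game of all four
#' conditions), \code{"pain_easy"} and \code{"pain_hard"} (pain vs no-pain
#' within one demand level, duration-matched per participant). For the pain
#' tasks both the pain and the no-pain session are limited to the first T
#' seconds of the game, T being that participant's immersion duration, so the
#' two classes span equal wall-clock time by construction.
#'
#' @param sessions List of fully preprocessed \code{hemodynamic_series} for
#'   the game conditions of a cohort.
#' @param task One of \code{"demand"}, \code{"pain_easy"}, \code{"pain_hard"}.
#' @param stream Feature stream: \code{"fnirs"} (96 columns) or \code{"hr"}
#'   (6 columns).
#' @return Object of class \code{"labelled_dataset"}: feature matrix
#'   \code{x}, factor \code{y} (positive class last: Hard / pain),
#'   participant \code{groups}, \code{task}, \code{stream}, and a
#'   \code{balance} table of class counts.
#' @export
build_task_dataset <- function(sessions, task = c("demand", "pain_easy",
                                                  "pain_hard"),
                               stream = c("fnirs", "hr")) {
  task <- match.arg(task)
  stream <- match.arg(stream)
  conds <- vapply(sessions, function(s) s$condition, character(1))
  pids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (task == "demand") {
    keep <- conds %in% c("easy", "hard", "easy_pain", "hard_pain")
    feats <- assemble_features(sessions[keep])
    y <- factor(feats$demand, levels = c("Easy", "Hard"))
  } else {
    demand <- if (task == "pain_easy") "easy" else "hard"
    pain_cond <- paste0(demand, "_pain")
    parts <- intersect(pids[conds == demand], pids[conds == pain_cond])
    if (!length(parts)) stop("no participants with both ", demand, " and ",
                             pain_cond, " sessions")
    feats <- NULL
    for (p in parts) {
      ps <- sessions[[which(pids == p & conds == pain_cond)[1]]]
      ns <- sessions[[which(pids == p & conds == demand)[1]]]
      m <- match_durations(ps, ns)
      feats <- rbind(feats,
                     assemble_features(list(ps, ns),
                                       max_duration_s = m$duration_s))
    }
    y <- factor(feats$pain, levels = c("no_pain", "pain"))
  }
  x <- as.matrix(feats[, feature_columns(stream)])
  # a zero-variance window leaves its Pearson feature missing (by contract);
  # classifiers need complete rows, so impute the column mean
  n_imputed <- sum(is.na(x))
  if (n_imputed) {
    for (j in which(colSums(is.na(x)) > 0)) {
      mu <- mean(x[, j], na.rm = TRUE)
      x[is.na(x[, j]), j] <- if (is.finite(mu)) mu else 0
    }
  }
  structure(list(x = x, y = y, groups = feats$participant_id,
                 task = task, stream = stream,
                 balance = table(y), n_imputed = n_imputed),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat("Labelled dataset:", x$task, "task,", x$stream, "features -",
      nrow(x$x), "epochs x", ncol(x$x), "features,",
      length(unique(x$groups)), "participants\n")
  print(x$balance)
  invisible(x)
}
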