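#' Complete patient-days as a question matrix
#'
#' Rows are (patient, date) days on which all 11 questions were answered —
#' the only days usable for discovering the question grouping. Columns
#' follow the canonical order of [question_ids].
#'
#' @param q_table A `questionnaire_table`.
#' @return Numeric matrix (days x 11) with rownames `patient_id/date`.
#' @export
select_complete_days <- function(q_table) {
  if (!nrow(q_table)) {
    stop("questionnaire table is empty", call. = FALSE)
  }
  key <- paste(q_table$patient_id, q_table$date, sep = "/")
  counts <- table(key)
  complete <- names(counts)[counts == length(question_ids)]
  if (!length(complete)) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(question_ids),
                dimnames = list(NULL, question_ids))
    return(m)
  }
  sub <- q_table[key %in% complete, , drop = FALSE]
  skey <- paste(sub$patient_id, sub$date, sep = "/")
  m <- matrix(NA_real_, nrow = length(complete), ncol = length(question_ids),
              dimnames = list(complete, question_ids))
  m[cbind(match(skey, complete), match(sub$question, question_ids))] <- sub$value
  m
}

#' Principal components of the question correlation matrix
#'
#' Eigen-decomposition of the correlation matrix of the columns (variables
#' are standardized, so eigenvalues sum to the number of questions).
#' Loadings are scaled such that the squared loadings of a component sum to
#' its eigenvalue. When `k` is not given, components with eigenvalue > 1 are
#' retained (Kaiser criterion).
#'
#' @param x Numeric matrix of complete observations (rows) x variables.
#' @param k Number of components to retain; `NULL` for eigenvalue > 1.
#' @return A `pca_loadings` object: list with `loadings` (variables x k),
#'   `eigenvalues` (all p), `explained` (percent of total variance, all p),
#'   `k`.
#' @export
principal_components <- function(x, k = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) {
    stop("need at least 2 rows", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(x)[which(sds == 0 | is.na(sds))[1]]
    stop("column '", bad, "' has zero variance", call. = FALSE)
  }
  r <- stats::cor(x)
  e <- eigen(r, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (is.null(k)) {
    k <- max(1L, sum(ev > 1))
  }
  if (k > ncol(x)) {
    stop("k exceeds the number of variables", call. = FALSE)
  }
  load <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  # sign convention: largest-magnitude loading of each component positive
  load <- fix_column_signs(load)
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(loadings = load,
                 eigenvalues = ev,
                 explained = 100 * ev / ncol(x),
                 k = k),
            class = "pca_loadings")
}

fix_column_signs <- function(load) {
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
    }
  }
  load
}

#' @export
print.pca_loadings <- function(x, ...) {
  cat("<pca_loadings> ", nrow(x$loadings), " variables, ", x$k,
      " retained components\n", sep = "")
  cat("  eigenvalues:", paste(sprintf("%.2f", x$eigenvalues), collapse = " "),
      "\n")
  cat(sprintf("  explained by retained: %.1f%%\n",
              sum(x$explained[seq_len(x$k)])))
  invisible(x)
}

#' Varimax rotation of retained loadings
#'
#' Orthogonal rotation maximizing the varimax criterion (variance of squared
#' loadings per factor) with Kaiser row-normalization, the standard route to
#' simple structure. Column signs are fixed so each factor's
#' largest-magnitude loading is positive.
#'
#' @param loadings A `pca_loadings` object or a bare loadings matrix.
#' @param k Number of components to rotate (default: all columns).
#' @param eps Convergence tolerance passed to [stats::varimax()].
#' @return A `rotated_loadings` object: list with `loadings`
#'   (variables x k, rotated), `rotmat` (orthonormal rotation matrix),
#'   `criterion` (varimax criterion value of the result).
#' @export
varimax_rotate <- function(loadings, k = NULL, eps = 1e-6) {
  l <- if (inherits(loadings, "pca_loadings")) loadings$loadings else
    as.matrix(loadings)
  if (is.null(k)) {
    k <- ncol(l)
  }
  if (k < 2L) {
    stop("varimax rotation needs at least 2 components", call. = FALSE)
  }
  l <- l[, seq_len(k), drop = FALSE]
  v <- stats::varimax(l, normalize = TRUE, eps = eps)
  rot <- unclass(v$loadings)
  signs <- vapply(seq_len(k), function(j) {
    if (rot[which.max(abs(rot[, j])), j] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(rot, 2, signs, "*")
  rotmat <- v$rotmat %*% diag(signs, k)
  dimnames(rot) <- list(rownames(l), paste0("Factor", seq_len(k)))
  structure(list(loadings = rot, rotmat = rotmat,
                 criterion = varimax_criterion(rot)),
            class = "rotated_loadings")
}

#' Varimax criterion value of a loadings matrix
#'
#' Sum over factors of the variance of squared Kaiser-normalized loadings;
#' the objective [varimax_rotate()] maximizes. Exported so alternative
#' rotations can be compared.
#'
#' @param loadings Numeric matrix (variables x factors).
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings) {
  l <- as.matrix(loadings)
  h <- sqrt(rowSums(l^2))
  h[h == 0] <- 1
  ln <- l / h
  sq <- ln^2
  sum(apply(sq, 2, function(col) mean(col^2) - mean(col)^2))
}

#' @export
print.rotated_loadings <- function(x, ...) {
  cat("<rotated_loadings> ", nrow(x$loadings), " variables x ",
      ncol(x$loadings), " factors (varimax criterion ",
      sprintf("%.4f", x$criterion), ")\n", sep = "")
  print(round(x$loadings, 2))
  invisible(x)
}

#' Biomarker definition: a named, ordered question subset
#'
#' @param name Biomarker name (e.g. `"WeBe-i"`).
#' @param questions Character vector of contributing question ids.
#' @return A `biomarker_definition` object.
#' @export
biomarker_definition <- function(name, questions) {
  questions <- as.character(questions)
  if (!all(questions %in% question_ids)) {
    stop("unknown question id(s): ",
         paste(setdiff(questions, question_ids), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, questions = questions),
            class = "biomarker_definition")
}

#' @export
print.biomarker_definition <- function(x, ...) {
  cat("<biomarker_definition> ", x$name, ": ",
      paste(x$questions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Assign questions to biomarkers from rotated loadings
#'
#' Each question goes to the factor where it has its largest absolute
#' rotated loading (ties broken toward the lowest factor index); factors are
#' then merged into named biomarkers per `merge_map`. The default map merges
#' factors 1 and 3 into the wellbeing index WeBe-i and keeps factor 2 as the
#' motivation/self-confidence index MotSC-i, the grouping used in clinical
#' deployment (the third factor collects the three-alternative questions,
#' which behave as wellbeing items).
#'
#' @param rotated A `rotated_loadings` object or bare rotated matrix.
#' @param merge_map Named list: biomarker name -> integer vector of factor
#'   indices.
#' @return List of [biomarker_definition()] objects, in `merge_map` order.
#' @export
assign_questions <- function(rotated,
                             merge_map = list("WeBe-i" = c(1L, 3L),
                                              "MotSC-i" = 2L)) {
  l <- if (inherits(rotated, "rotated_loadings")) rotated$loadings else
    as.matrix(rotated)
  k <- ncol(l)
  idx <- unlist(merge_map)
  if (any(idx < 1L | idx > k)) {
    stop("merge_map references factor index outside 1..", k, call. = FALSE)
  }
  # max.col with ties.method "first" = lowest factor index wins on ties
  best <- max.col(abs(l), ties.method = "first")
  qnames <- rownames(l)
  if (is.null(qnames)) {
    qnames <- paste0("V", seq_len(nrow(l)))
  }
  lapply(stats::setNames(names(merge_map), names(merge_map)), function(nm) {
    biomarker_definition(nm, qnames[best %in% merge_map[[nm]]])
  })
}
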