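#' Per-condition thickness summaries and error percentages
#'
#' Groups slice records by (tissue, step size, speed) and computes n, mean,
#' sample SD and the thickness error
#' `error_pct = (mean - step_size) / step_size * 100`, the accuracy metric
#' comparing the actual hydrated thickness with the nominal vibratome step.
#' Conditions with no records yield no row: missing cells are explicitly
#' absent, never zeros.
#'
#' @param records Data frame of slice records with columns `tissue`,
#'   `step_size` (um), `speed` (mm/s), `thickness` (um, > 0).
#'
#' @return Data frame with columns `tissue`, `step_size`, `speed`, `n`,
#'   `mean_um`, `sd_um`, `error_pct`, ordered by tissue, step, speed.
#' @export
summarize_combos <- function(records) {
  check_records(records)
  key <- interaction(records$tissue, records$step_size, records$speed,
                     drop = TRUE)
  parts <- split(records, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    m <- mean(p$thickness)
    data.frame(
      tissue = p$tissue[1L], step_size = p$step_size[1L], speed = p$speed[1L],
      n = nrow(p), mean_um = m,
      sd_um = if (nrow(p) > 1L) stats::sd(p$thickness) else NA_real_,
      error_pct = (m - p$step_size[1L]) / p$step_size[1L] * 100,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$tissue, out$step_size, out$speed), ]
  rownames(out) <- NULL
  out
}

#' Overall thickness error per tissue
#'
#' Arithmetic mean of the per-condition error percentages over all defined
#' (step size, speed) conditions of a tissue — the single-number accuracy
#' summary. Conditions where no slices were obtained contribute nothing.
#'
#' @param combos Per-condition summaries from [summarize_combos()], or any
#'   data frame with `tissue` and `error_pct` columns.
#'
#' @return Data frame with columns `tissue`, `n_combos`,
#'   `overall_error_pct`, at full precision.
#' @export
overall_error <- function(combos) {
  if (!is.data.frame(combos) || !all(c("tissue", "error_pct") %in% names(combos))) {
    stop("`combos` must have columns tissue and error_pct", call. = FALSE)
  }
  combos <- combos[!is.na(combos$error_pct), ]
  if (nrow(combos) == 0L) {
    stop("no conditions with a defined error percentage", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(combos, combos$tissue), function(p) {
    data.frame(tissue = p$tissue[1L], n_combos = nrow(p),
               overall_error_pct = mean(p$error_pct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fixed-effects ANOVA of slice thickness
#'
#' One- or two-way analysis of variance of thickness on the sectioning
#' factors. With two factors the model includes the interaction
#' (`thickness ~ A * B`) and every cell must hold at least 2 records;
#' balanced designs use the classical sequential decomposition (Type I,
#' which coincides with Type II when balanced), unbalanced designs use
#' Type-II sums of squares.
#'
#' @param records Slice records (see [summarize_combos()]); a single tissue
#'   is expected — subset first.
#' @param factors Character vector of 1 or 2 record columns to use as fixed
#'   factors, e.g. `c("step_size", "speed")` or `"step_size"`.
#' @param interaction Include the A:B interaction (two factors only).
#'
#' @return Data frame with columns `term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p_value`; the last row is the residual.
#' @export
#' @examples
#' d <- generate_study(reference_design("pfa_brain"), seed = 7)
#' thickness_anova(d, c("step_size", "speed"))
thickness_anova <- function(records, factors = c("step_size", "speed"),
                            interaction = TRUE) {
  check_records(records, require_positive = FALSE)
  if (!all(factors %in% names(records))) {
    stop("all `factors` must be columns of `records`", call. = FALSE)
  }
  if (!length(factors) %in% 1:2) {
    stop("ANOVA supports 1 or 2 factors", call. = FALSE)
  }
  df <- data.frame(thickness = records$thickness)
  for (f in factors) {
    fac <- factor(records[[f]])
    if (nlevels(fac) < 2L) {
      stop(sprintf("factor '%s' has fewer than 2 levels", f), call. = FALSE)
    }
    df[[f]] <- fac
  }

  if (length(factors) == 2L && interaction) {
    cell_n <- table(df[[factors[1L]]], df[[factors[2L]]])
    if (any(cell_n > 0 & cell_n < 2)) {
      stop(paste0("some cells hold a single record; the interaction term ",
                  "cannot be estimated - rerun with interaction = FALSE"),
           call. = FALSE)
    }
    balanced <- length(unique(cell_n[cell_n > 0])) == 1L && all(cell_n > 0)
    form <- stats::as.formula(
      sprintf("thickness ~ %s * %s", factors[1L], factors[2L]))
  } else {
    balanced <- TRUE
    form <- stats::as.formula(
      paste("thickness ~", paste(factors, collapse = " + ")))
  }

  if (balanced) {
    fit <- stats::aov(form, data = df)
    tab <- summary(fit)[[1L]]
    out <- data.frame(
      term = trimws(rownames(tab)), df = tab[["Df"]],
      sumsq = tab[["Sum Sq"]], meansq = tab[["Mean Sq"]],
      statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]],
      stringsAsFactors = FALSE
    )
  } else {
    fit <- stats::lm(form, data = df)
    tab <- car::Anova(fit, type = 2)
    out <- data.frame(
      term = trimws(rownames(tab)), df = tab[["Df"]],
      sumsq = tab[["Sum Sq"]],
      meansq = tab[["Sum Sq"]] / tab[["Df"]],
      statistic = tab[["F value"]], p_value = tab[["Pr(>F)"]],
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Tukey HSD comparisons with a compact letter display
#'
#' All-pairwise post-hoc comparisons after ANOVA, using honestly-significant-
#' difference adjusted p-values from the studentized-range distribution, and
#' the familiar letter labels: two groups share a letter exactly when their
#' adjusted p-value is at least `alpha`. By default groups are the
#' individual (factor-combination) cells; pass a single factor name to
#' compare its marginal levels instead.
#'
#' @param records Slice records for one tissue.
#' @param factors Columns defining the groups (cells are their
#'   combinations).
#' @param alpha Significance level (default 0.05).
#'
#' @return An object of class `tukey_grouping`: list with `groups` (data
#'   frame: `group`, `n`, `mean`, `letters`), `pairwise` (data frame:
#'   `group1`, `group2`, `diff`, `p_adj`) and `alpha`.
#' @export
tukey_grouping <- function(records, factors = c("step_size", "speed"),
                           alpha = 0.05) {
  check_records(records, require_positive = FALSE)
  if (!all(factors %in% names(records))) {
    stop("all `factors` must be columns of `records`", call. = FALSE)
  }
  g <- interaction(lapply(factors, function(f) records[[f]]),
                   drop = TRUE, sep = "x")
  if (nlevels(g) < 2L) {
    stop("Tukey comparisons need at least 2 groups", call. = FALSE)
  }
  df <- data.frame(thickness = records$thickness, g = g)
  fit <- stats::aov(thickness ~ g, data = df)
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g

  lev <- levels(g)
  all_pairs <- utils::combn(lev, 2L, simplify = FALSE)
  pmat <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  pairs <- vector("list", nrow(th))
  for (i in seq_len(nrow(th))) {
    rn <- rownames(th)[i]
    hit <- Filter(function(p) {
      rn == paste0(p[1L], "-", p[2L]) || rn == paste0(p[2L], "-", p[1L])
    }, all_pairs)
    if (length(hit) != 1L) {
      stop(sprintf("cannot resolve Tukey comparison '%s' to a group pair", rn),
           call. = FALSE)
    }
    pairs[[i]] <- hit[[1L]]
    pmat[hit[[1L]][1L], hit[[1L]][2L]] <-
      pmat[hit[[1L]][2L], hit[[1L]][1L]] <- th[i, "p adj"]
  }
  letters <- letter_display(pmat, alpha = alpha)

  groups <- data.frame(
    group = lev,
    n = as.integer(table(g)[lev]),
    mean = tapply(df$thickness, df$g, mean)[lev],
    letters = letters[lev],
    stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL
  pairwise <- data.frame(
    group1 = vapply(pairs, `[`, "", 1L),
    group2 = vapply(pairs, `[`, "", 2L),
    diff = th[, "diff"], p_adj = th[, "p adj"],
    stringsAsFactors = FALSE
  )
  rownames(pairwise) <- NULL
  structure(list(groups = groups, pairwise = pairwise, alpha = alpha),
            class = "tukey_grouping")
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat(sprintf("Tukey HSD grouping (alpha = %g)\n", x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Assigns letters to groups so that two groups share a letter if and only
#' if their pairwise p-value is at least `alpha` — the display used under
#' bar plots of group means. Implemented with the insert-and-absorb
#' algorithm: start from one set holding all groups, split every set that
#' contains a significantly different pair, then absorb sets contained in
#' others.
#'
#' @param pmat Symmetric matrix of pairwise p-values with group names on
#'   both dimnames (diagonal ignored).
#' @param alpha Significance level.
#'
#' @return Named character vector of letter strings, one per group.
#' @export
#' @examples
#' p <- matrix(c(1, .8, .01, .8, 1, .03, .01, .03, 1), 3, 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' letter_display(p)
letter_display <- function(pmat, alpha = 0.05) {
  if (!is.matrix(pmat) || nrow(pmat) != ncol(pmat) || nrow(pmat) < 2L) {
    stop("`pmat` must be a square matrix for >= 2 groups", call. = FALSE)
  }
  k <- nrow(pmat)
  nm <- rownames(pmat)
  if (is.null(nm)) nm <- as.character(seq_len(k))

  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if (pmat[i, j] < alpha) {
        new_sets <- list()
        for (s in sets) {
          if (i %in% s && j %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        sets <- absorb_sets(new_sets)
      }
    }
  }
  sets <- sets[vapply(sets, length, 0L) > 0L]
  sets <- sets[order(vapply(sets, min, 0L))]

  labels <- make_letter_labels(length(sets))
  out <- vapply(seq_len(k), function(g) {
    paste(labels[vapply(sets, function(s) g %in% s, TRUE)], collapse = "")
  }, "")
  names(out) <- nm
  out
}

# Drop sets that are subsets of (or equal to) another retained set.
absorb_sets <- function(sets) {
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i == j || !keep[j]) next
      si <- sets[[i]]; sj <- sets[[j]]
      if (length(si) <= length(sj) && all(si %in% sj) &&
          !(length(si) == length(sj) && i < j)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets[keep]
}

make_letter_labels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  c(letters, vapply(seq_len(n - 26L), function(i) {
    paste0(letters[(i - 1L) %/% 26L + 1L], letters[(i - 1L) %% 26L + 1L])
  }, ""))
}

check_records <- function(records, require_positive = TRUE) {
  req <- c("tissue", "step_size", "speed", "thickness")
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  if (!all(req %in% names(records))) {
    stop(sprintf("`records` must contain columns: %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  }
  if (require_positive &&
      (any(records$thickness <= 0) || any(records$step_size <= 0) ||
       any(records$speed <= 0))) {
    stop("thickness, step_size and speed must all be positive", call. = FALSE)
  }
  invisible(records)
}
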