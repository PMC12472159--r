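# Cohen's-kappa agreement between manual and automatic lesion-highlight
# indicators, with the table conventions: kappa to 4 decimals, "N/A" when
# chance agreement is 1 (both raters constant and identical), and an en
# dash for empty strata.

#' Cohen's kappa for two binary raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e = sum_c p_a(c) p_b(c)` the chance agreement from the raters'
#' marginals. When both raters are constant *and identical*, `p_e = 1` and
#' kappa is undefined (`NA` status); an empty stratum (`n = 0`) renders as a
#' dash. When exactly one rater is constant, `p_o = p_e` and kappa is 0.
#' When the raters are constant on *different* categories, `p_e = 0` and
#' kappa is 0 as well (the verbal "no variability" rule is ambiguous there;
#' this implementation only declares N/A at `p_e = 1`).
#'
#' @param a,b Binary vectors (0/1 or logical) in identical image order, or
#'   `rater_vector` objects with matching `image_ids`.
#' @return A `kappa_cell`: list with `value`, `n`, `status` in
#'   `c("ok", "na", "dash")`.
#' @export
cohens_kappa <- function(a, b) {
  if (inherits(a, "rater_vector") && inherits(b, "rater_vector")) {
    if (!identical(a$image_ids, b$image_ids)) {
      stop_fundus("cohens_kappa: raters cover different image sets",
                  "fundusXAI_input_error")
    }
    a <- a$labels; b <- b$labels
  }
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  if (length(a) != length(b)) {
    stop_fundus("cohens_kappa: rater vectors differ in length",
                "fundusXAI_input_error")
  }
  n <- length(a)
  if (n == 0L) return(new_kappa_cell(NA_real_, 0L, "dash"))
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe == 1) return(new_kappa_cell(NA_real_, n, "na"))
  new_kappa_cell((po - pe) / (1 - pe), n, "ok")
}

new_kappa_cell <- function(value, n, status) {
  structure(list(value = value, n = as.integer(n), status = status),
            class = "kappa_cell")
}

#' @export
print.kappa_cell <- function(x, ...) {
  cat(sprintf("<kappa %s (n=%d)>\n", format_kappa(x), x$n))
  invisible(x)
}

#' Render a kappa cell the way agreement tables print it
#'
#' @param cell A `kappa_cell`.
#' @return `"N/A"`, `"-"`, or the value at 4 decimals.
#' @export
format_kappa <- function(cell) {
  switch(cell$status,
         dash = "-",
         na = "N/A",
         ok = sprintf("%.4f", cell$value))
}

#' Ordered binary rater vector
#'
#' @param image_ids Character vector of image identifiers.
#' @param labels Binary labels, one per image (1 = lesion highlighted).
#' @return A `rater_vector`.
#' @export
rater_vector <- function(image_ids, labels) {
  if (length(image_ids) != length(labels)) {
    stop_fundus("rater_vector: labels length must equal image_ids length",
                "fundusXAI_input_error")
  }
  structure(list(image_ids = as.character(image_ids),
                 labels = as.integer(as.logical(labels))),
            class = "rater_vector")
}

#' Agreement table between manual annotations and automatic overlap records
#'
#' Joins a manual annotation table (one row per image, method and lesion:
#' was the lesion highlighted in the overlay?) with automatic overlap
#' records, stratifies by (method, DR grade, prediction correctness), and
#' computes Cohen's kappa per lesion type in each stratum.
#'
#' @param manual Data.frame with columns `image_id`, `method`, `lesion`,
#'   `highlighted` (0/1).
#' @param records Overlap records data.frame (see [evaluate_image()]) with
#'   columns `image_id`, `method`, `lesion`, `grade`, `correct`, `hit`.
#' @param lesions Lesion types to tabulate (default: those in `manual`).
#' @param methods Methods to tabulate (default: those in `records`).
#' @return A long data.frame: method, grade, correct, lesion, kappa, n,
#'   status, rendered.
#' @export
build_agreement_table <- function(manual, records, lesions = NULL,
                                  methods = NULL) {
  req_m <- c("image_id", "method", "lesion", "highlighted")
  req_r <- c("image_id", "method", "lesion", "grade", "correct", "hit")
  if (!all(req_m %in% names(manual)) || !all(req_r %in% names(records))) {
    stop_fundus("build_agreement_table: missing required columns",
                "fundusXAI_input_error")
  }
  lesions <- lesions %||% sort(unique(manual$lesion))
  methods <- methods %||% sort(unique(records$method))
  only_manual <- setdiff(unique(manual$image_id), unique(records$image_id))
  only_auto <- setdiff(unique(records$image_id), unique(manual$image_id))
  if (length(only_manual) || length(only_auto)) {
    stop_fundus(sprintf(
      "image sets differ between manual and automatic sources (manual-only: %s; automatic-only: %s)",
      paste(only_manual, collapse = ","), paste(only_auto, collapse = ",")),
      "fundusXAI_data_error")
  }
  out <- list()
  for (method in methods) {
    rmeth <- records[records$method == method, , drop = FALSE]
    mmeth <- manual[manual$method == method, , drop = FALSE]
    for (g in sort(unique(records$grade))) {
      for (corr in c(TRUE, FALSE)) {
        ids <- sort(unique(rmeth$image_id[rmeth$grade == g &
                                            rmeth$correct == corr]))
        for (lt in lesions) {
          cell <- if (length(ids) == 0L) {
            new_kappa_cell(NA_real_, 0L, "dash")
          } else {
            auto <- rmeth[rmeth$lesion == lt &
                            match(rmeth$image_id, ids, nomatch = 0L) > 0L, ]
            man <- mmeth[mmeth$lesion == lt &
                           match(mmeth$image_id, ids, nomatch = 0L) > 0L, ]
            av <- setNames(rep(0L, length(ids)), ids)
            mv <- av
            av[auto$image_id] <- as.integer(auto$hit)
            mv[man$image_id] <- as.integer(man$highlighted)
            cohens_kappa(mv, av)
          }
          out[[length(out) + 1L]] <- data.frame(
            method = method, grade = g, correct = corr, lesion = lt,
            kappa = if (cell$status == "ok") cell$value else NA_real_,
            n = cell$n, status = cell$status, rendered = format_kappa(cell),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Render an agreement table in wide per-grade layout
#'
#' One row per (method, grade); lesion columns grouped under correct then
#' incorrect predictions, each cell `"N/A"`, `"-"`, or kappa at 4 decimals.
#'
#' @param tab Long table from [build_agreement_table()].
#' @param lesions Column order (default: order of appearance).
#' @return Character data.frame.
#' @export
render_agreement_table <- function(tab, lesions = NULL) {
  lesions <- lesions %||% unique(tab$lesion)
  rows <- list()
  for (method in unique(tab$method)) {
    for (g in sort(unique(tab$grade))) {
      row <- list(method = method, grade = g)
      for (corr in c(TRUE, FALSE)) {
        pre <- if (corr) "correct" else "incorrect"
        for (lt in lesions) {
          cell <- tab[tab$method == method & tab$grade == g &
                        tab$correct == corr & tab$lesion == lt, ]
          row[[paste0(pre, "_", lt)]] <-
            if (nrow(cell)) cell$rendered[1] else "-"
        }
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
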