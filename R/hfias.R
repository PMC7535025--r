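the_hfias_env <- new.env(parent = emptyenv())

# FANTA HFIAS v3 category decision table: per (item, frequency) the household
# food-insecurity (access) category that condition alone implies; the
# household's category is the most severe condition present. Shipped as a CSV
# so tests can be table-driven.
hfias_table <- function() {
  if (is.null(the_hfias_env$table)) {
    path <- system.file("extdata", "hfias_category_table.csv", package = "anemetrics")
    tb <- utils::read.csv(path)
    the_hfias_env$table <- tb
    # lookup matrix: rows items 1-9, cols frequencies 0-3
    m <- matrix(1L, nrow = 9, ncol = 4)
    m[cbind(tb$item, tb$frequency + 1L)] <- as.integer(tb$category)
    the_hfias_env$lookup <- m
  }
  the_hfias_env$table
}

hfias_cols <- function(kind = c("freq", "occ")) {
  kind <- match.arg(kind)
  sprintf("hfias%d_%s", 1:9, kind)
}

validate_hfias <- function(data) {
  fc <- hfias_cols("freq")
  oc <- hfias_cols("occ")
  missing <- setdiff(c(fc, oc), names(data))
  if (length(missing)) {
    abort(paste("missing HFIAS columns:", paste(missing, collapse = ", ")))
  }
  fq <- as.matrix(data[fc])
  oq <- as.matrix(data[oc])
  if (any(!fq %in% 0:3) || any(!oq %in% 0:1)) {
    abort("HFIAS frequencies must be 0-3 and occurrences 0/1")
  }
  bad <- which(rowSums(fq > 0 & oq == 0) > 0)
  if (length(bad)) {
    abort(sprintf(
      "HFIAS frequency recorded without occurrence; offending rows: %s",
      paste(utils::head(bad, 10L), collapse = ", ")
    ))
  }
  fq
}

#' HFIAS food-insecurity score
#'
#' The Household Food Insecurity Access Scale score: the sum of the nine item
#' frequency codes (0 never, 1 rarely, 2 sometimes, 3 often), ranging 0-27.
#'
#' @param data A data frame with columns `hfias1_occ`..`hfias9_occ` and
#'   `hfias1_freq`..`hfias9_freq`.
#' @return The input with an `hfias_score` integer column appended.
#' @export
hfias_score <- function(data) {
  fq <- validate_hfias(data)
  dplyr::mutate(as_tibble(data), hfias_score = as.integer(rowSums(fq)))
}

#' HFIAS four-level food-insecurity category
#'
#' Applies the FANTA HFIAS v3 categorisation: each (item, frequency)
#' combination implies a severity level (see the packaged decision table
#' `hfias_category_table.csv`), and the household is assigned its most severe
#' condition -- from worry about food (mild, unless rarely) up to spending a
#' whole day and night without eating (severe).
#'
#' @inheritParams hfias_score
#' @return The input with an ordered factor column `hfias_category`
#'   (`food_secure < mild < moderate < severe`) appended.
#' @export
hfias_category <- function(data) {
  fq <- validate_hfias(data)
  hfias_table()
  lk <- the_hfias_env$lookup
  cat_code <- apply(fq, 1L, function(row) max(lk[cbind(1:9, row + 1L)]))
  levels <- c("food_secure", "mild", "moderate", "severe")
  dplyr::mutate(
    as_tibble(data),
    hfias_category = factor(levels[cat_code], levels = levels, ordered = TRUE)
  )
}
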