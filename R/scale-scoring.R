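#' Define a Likert scale
#'
#' @param name Scale label.
#' @param n_items Number of items.
#' @param range Length-2 response range, e.g. `c(1, 5)`.
#' @param reverse Integer indices of reverse-scored items.
#' @return A `scale_spec` list.
#' @export
scale_spec <- function(name, n_items, range, reverse = integer()) {
  n_items <- as.integer(n_items)
  reverse <- as.integer(reverse)
  if (n_items < 1) abort_param("`n_items` must be positive.")
  if (length(range) != 2 || range[1] >= range[2]) {
    abort_param("`range` must be c(min, max) with min < max.")
  }
  if (length(reverse) > 0 && (min(reverse) < 1 || max(reverse) > n_items)) {
    abort_param("`reverse` indices must lie in 1..n_items.")
  }
  structure(
    list(name = name, n_items = n_items, range = as.numeric(range),
         reverse = reverse),
    class = "scale_spec"
  )
}

#' 20-item UCLA loneliness scale specification
#'
#' 11 negatively worded (lonely) and 9 positively worded (non-lonely) items;
#' the positive items are reverse-scored so that higher scores mean greater
#' loneliness. The published item order varies across translations, so the
#' reverse-scored set is configuration, not a constant; the default is the
#' conventional set for the 20-item version. The response format is 1-4
#' (never..often) by default and configurable.
#'
#' @param range Response range (default `c(1, 4)`).
#' @param reverse Indices of the reverse-scored (non-lonely) items.
#' @return A `scale_spec`.
#' @export
ucla_spec <- function(range = c(1, 4),
                      reverse = c(1L, 5L, 6L, 9L, 10L, 15L, 16L, 19L, 20L)) {
  scale_spec("UCLA loneliness", 20L, range, reverse)
}

#' 15-item essential resilience scale specification
#'
#' Five-point agreement format; higher scores indicate greater psychological
#' resources. No reverse-scored items by default.
#'
#' @param reverse Indices of reverse-scored items (default none).
#' @return A `scale_spec`.
#' @export
ers_spec <- function(reverse = integer()) {
  scale_spec("Essential resilience", 15L, c(1, 5), reverse)
}

#' 20-item PANAS specification
#'
#' Two 10-item subscales (positive and negative activation) on a 1-5 intensity
#' format, scored as subscale means with no reverse coding. Item positions of
#' the subscales are configurable; the default is the standard ordering.
#'
#' @param pa_items,na_items Item indices of the two subscales.
#' @return A `scale_spec` with `pa_items`/`na_items` fields.
#' @export
panas_spec <- function(pa_items = c(1L, 3L, 5L, 9L, 10L, 12L, 14L, 16L, 17L, 19L),
                       na_items = c(2L, 4L, 6L, 7L, 8L, 11L, 13L, 15L, 18L, 20L)) {
  if (length(pa_items) != 10L || length(na_items) != 10L ||
      length(intersect(pa_items, na_items)) > 0) {
    abort_param("PANAS subscales must be two disjoint sets of 10 items.")
  }
  spec <- scale_spec("PANAS", 20L, c(1, 5))
  spec$pa_items <- as.integer(pa_items)
  spec$na_items <- as.integer(na_items)
  spec
}

# Accept a tibble with person_id + item columns, or a plain matrix, and
# return a numeric matrix with person ids as rownames.
as_item_matrix <- function(items) {
  if (is.matrix(items)) {
    m <- items
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    storage.mode(m) <- "double"
    return(m)
  }
  items <- as_tibble(items)
  if (!"person_id" %in% names(items)) {
    abort_format("Item tables need a `person_id` column (or pass a matrix).")
  }
  m <- as.matrix(items[setdiff(names(items), "person_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(items$person_id)
  m
}

check_item_range <- function(m, spec) {
  bad <- which(!is.na(m) & (m < spec$range[1] | m > spec$range[2]))
  if (length(bad) > 0) {
    abort_integrity(sprintf(
      "%d response(s) outside [%g, %g] on the %s scale.",
      length(bad), spec$range[1], spec$range[2], spec$name
    ))
  }
  if (ncol(m) != spec$n_items) {
    abort_format(sprintf(
      "%s scale expects %d items, got %d columns.",
      spec$name, spec$n_items, ncol(m)
    ))
  }
  invisible(m)
}

#' Reverse-code Likert responses
#'
#' Maps `x` to `min + max - x`. Applying it twice restores the input.
#'
#' @param x Numeric vector/matrix of responses.
#' @param range Length-2 response range.
#' @return Reverse-coded values.
#' @export
reverse_code <- function(x, range) {
  range[1] + range[2] - x
}

#' Score a Likert scale as the (reverse-coded) item mean
#'
#' Reverse-scored items are mapped `x -> min + max - x`, then the score is the
#' person-wise item mean, so scores live on the response scale. Missing items
#' are tolerated up to `1 - min_prop` of the scale (person-mean imputation via
#' the mean of the answered items); below that the score is `NA`.
#'
#' @param items Tibble with `person_id` plus item columns, or a numeric
#'   matrix (persons x items).
#' @param spec A [scale_spec()].
#' @param min_prop Minimum proportion of answered items (default 0.8).
#' @return Tibble with `person_id` and `score`.
#' @export
score_likert_scale <- function(items, spec, min_prop = 0.8) {
  m <- as_item_matrix(items)
  check_item_range(m, spec)
  if (length(spec$reverse) > 0) {
    m[, spec$reverse] <- reverse_code(m[, spec$reverse], spec$range)
  }
  answered <- rowMeans(!is.na(m))
  score <- rowMeans(m, na.rm = TRUE)
  score[answered < min_prop] <- NA_real_
  score[is.nan(score)] <- NA_real_
  tibble(person_id = rownames(m), score = unname(score))
}

#' Score the PANAS into subscale means
#'
#' @param items Tibble or matrix of the 20 PANAS responses.
#' @param spec A [panas_spec()].
#' @param min_prop Minimum proportion of answered items per subscale.
#' @return Tibble with `person_id`, `pa`, `na`.
#' @export
score_panas <- function(items, spec = panas_spec(), min_prop = 0.8) {
  m <- as_item_matrix(items)
  check_item_range(m, spec)
  sub_score <- function(idx) {
    s <- m[, idx, drop = FALSE]
    answered <- rowMeans(!is.na(s))
    out <- rowMeans(s, na.rm = TRUE)
    out[answered < min_prop | is.nan(out)] <- NA_real_
    unname(out)
  }
  tibble(
    person_id = rownames(m),
    pa = sub_score(spec$pa_items),
    na = sub_score(spec$na_items)
  )
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`, with sample
#' (n-1) variances on complete cases.
#'
#' @param items Tibble or matrix of item responses (>= 2 items, >= 2 persons).
#' @return Alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(items) {
  m <- as_item_matrix(items)
  m <- m[complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2) abort_param("Cronbach's alpha needs at least 2 items.")
  if (nrow(m) < 2) abort_param("Cronbach's alpha needs at least 2 persons.")
  total_var <- var(rowSums(m))
  if (total_var <= 0) {
    abort_stat("Total-score variance is zero; alpha is undefined.")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
}

#' Test-retest reliability (Pearson correlation of paired scores)
#'
#' @param pre,post Numeric score vectors, or tibbles with `person_id` and
#'   `score` (joined on `person_id`).
#' @return Pearson r over complete pairs.
#' @export
retest_reliability <- function(pre, post) {
  if (is.data.frame(pre) || is.data.frame(post)) {
    pre <- as_tibble(pre); post <- as_tibble(post)
    joined <- left_join(pre, post, by = "person_id",
                        suffix = c("_pre", "_post"))
    x <- joined$score_pre; y <- joined$score_post
  } else {
    if (length(pre) != length(post)) {
      abort_param("`pre` and `post` must be paired (same length).")
    }
    x <- pre; y <- post
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort_param("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_stat("Zero variance in one wave; correlation is undefined.")
  }
  cor(x, y)
}

#' Build the person-level trait covariate table
#'
#' Trait composites are the mean of the pre- and post-wave scores (the traits
#' are treated as stable, with high retest reliability); centered versions
#' subtract the grand mean over the retained persons, so they sum to zero.
#'
#' @param res_pre,res_post Resilience score tibbles (`person_id`, `score`).
#' @param lon_pre,lon_post Loneliness score tibbles.
#' @param single_wave If `TRUE`, a person present in only one wave keeps that
#'   wave's score; otherwise this is an error.
#' @return Tibble of class `trait_table` with `person_id`, `res_raw`,
#'   `lon_raw`, `res_c`, `lon_c`.
#' @export
make_trait_table <- function(res_pre, res_post, lon_pre, lon_post,
                             single_wave = FALSE) {
  combine <- function(pre, post, label) {
    pre <- as_tibble(pre); post <- as_tibble(post)
    j <- dplyr::full_join(pre, post, by = "person_id",
                          suffix = c("_pre", "_post"))
    one_wave <- xor(is.na(j$score_pre), is.na(j$score_post))
    if (any(one_wave) && !single_wave) {
      abort_param(sprintf(
        "%d person(s) have a single %s wave; set `single_wave = TRUE` to use it.",
        sum(one_wave), label
      ))
    }
    j$raw <- rowMeans(cbind(j$score_pre, j$score_post), na.rm = TRUE)
    j$raw[is.nan(j$raw)] <- NA_real_
    j[c("person_id", "raw")]
  }
  res <- combine(res_pre, res_post, "resilience")
  lon <- combine(lon_pre, lon_post, "loneliness")
  out <- dplyr::full_join(res, lon, by = "person_id",
                          suffix = c("_res", "_lon"))
  names(out) <- c("person_id", "res_raw", "lon_raw")
  out$res_c <- out$res_raw - mean(out$res_raw, na.rm = TRUE)
  out$lon_c <- out$lon_raw - mean(out$lon_raw, na.rm = TRUE)
  structure(out, class = c("trait_table", class(tibble())))
}

# Internal constructor used by the simulator, where scale scores are drawn
# directly rather than built from item responses.
new_trait_table <- function(person_id, res_raw, lon_raw) {
  structure(
    tibble(
      person_id = as.character(person_id),
      res_raw = res_raw,
      lon_raw = lon_raw,
      res_c = res_raw - mean(res_raw),
      lon_c = lon_raw - mean(lon_raw)
    ),
    class = c("trait_table", class(tibble()))
  )
}
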