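# Episode tables -> model-ready matrices: numerics pass through with missing
# values preserved, categoricals are target encoded, condition-history flags
# become {0,1} columns. Encoding maps are fitted on the training cohort only
# and frozen, so that drift statistics on later cohorts are computed under
# the deployed model's view of the data.

#' Target-encode a categorical column
#'
#' Replaces each level by a smoothed mean of the binary outcome among
#' training rows carrying that level:
#' \deqn{enc(l) = (n_l \bar{y}_l + m \bar{y}) / (n_l + m)}
#' where \eqn{\bar{y}} is the global outcome mean (the prior). Levels unseen
#' at fit time map to the prior.
#'
#' @param column character/factor vector of level tokens.
#' @param outcome binary 0/1 vector, same length.
#' @param m smoothing weight (>= 0, default 10).
#' @return list with `encoded` (numeric vector in `[0,1]`) and `map`, a
#'   `target_encoding_map` (named level values, `prior`, `m`).
#' @export
#' @examples
#' target_encode(c("A", "A", "A", "B"), c(1, 1, 0, 0), m = 0)$map$levels
target_encode <- function(column, outcome, m = 10) {
  stop_if(length(column) == 0, "empty input")
  stop_if(length(column) != length(outcome), "column/outcome length mismatch")
  stop_if(!all(outcome %in% c(0, 1)), "outcome must be binary 0/1")
  stop_if(m < 0, "smoothing weight must be non-negative")
  column <- as.character(column)
  prior <- mean(outcome)
  n_l <- tapply(outcome, column, length)
  mean_l <- tapply(outcome, column, mean)
  enc <- (n_l * mean_l + m * prior) / (n_l + m)
  map <- structure(
    list(levels = setNames(as.numeric(enc), names(enc)), prior = prior, m = m),
    class = "target_encoding_map")
  list(encoded = as.vector(apply_encoding(map, column)), map = map)
}

#' Apply a fitted target-encoding map to new level tokens
#'
#' Unseen levels (including `NA`) map to the fitted prior; callers can
#' inspect which via the `new_levels` attribute, the observable trace of an
#' emergent category reaching a frozen encoder.
#'
#' @param map a `target_encoding_map`.
#' @param column character vector of level tokens.
#' @return numeric vector with attribute `new_levels` (character).
#' @export
apply_encoding <- function(map, column) {
  column <- as.character(column)
  v <- unname(map$levels[column])
  new <- setdiff(unique(column[is.na(v) | !column %in% names(map$levels)]),
                 names(map$levels))
  v[is.na(v)] <- map$prior
  attr(v, "new_levels") <- new
  v
}

#' Encode an episode table into a feature matrix
#'
#' Numerics pass through (missing preserved as `NA`, never imputed);
#' categoricals are target encoded; each `hx_*` flag becomes one `{0,1}`
#' column. With `maps = "fit"` the encodings are fitted on `table` (which
#' must carry outcomes) and returned for frozen reuse on later cohorts.
#'
#' @param table an episode table.
#' @param maps `"fit"` or the `maps` element of a previous fit.
#' @param m smoothing weight when fitting (default 10).
#' @return list: `X` numeric matrix (episodes x features, `NA` = missing),
#'   `maps` named list of `target_encoding_map`s, `column_meta` data.frame
#'   (`name`, `origin`), `new_category_events` data.frame (`feature`,
#'   `level`, `n`) of unseen levels hit when applying frozen maps.
#' @export
encode_table <- function(table, maps = "fit", m = 10) {
  num_names <- intersect(names(.numeric_defaults()), names(table))
  extra_num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       c(num_names, "outcome", "week",
                         grep("^hx_", names(table), value = TRUE)))
  num_names <- c(num_names, setdiff(extra_num, c("episode_id", "timestamp")))
  cat_names <- setdiff(names(table)[vapply(table, is.character, logical(1))],
                       c("episode_id", "cohort"))
  hx_names <- grep("^hx_", names(table), value = TRUE)

  fitting <- identical(maps, "fit")
  if (fitting) {
    stop_if(!"outcome" %in% names(table),
            "fitting encodings requires outcomes in the table")
    maps <- list()
  } else {
    stop_if(!all(cat_names %in% names(maps)),
            "fitted maps do not cover all categorical columns")
  }

  cols <- list()
  meta <- list()
  events <- list()
  for (nm in num_names) {
    cols[[nm]] <- as.numeric(table[[nm]])
    meta[[nm]] <- "numeric"
  }
  for (nm in cat_names) {
    if (fitting) {
      fit <- target_encode(table[[nm]], table$outcome, m = m)
      maps[[nm]] <- fit$map
      cols[[nm]] <- fit$encoded
    } else {
      cols[[nm]] <- apply_encoding(maps[[nm]], table[[nm]])
      new <- attr(cols[[nm]], "new_levels")
      if (length(new))
        events[[nm]] <- data.frame(
          feature = nm, level = new,
          n = vapply(new, function(l) sum(table[[nm]] == l, na.rm = TRUE),
                     numeric(1)),
          row.names = NULL)
    }
    meta[[nm]] <- "target_encoded"
  }
  for (nm in hx_names) {
    cols[[nm]] <- as.numeric(table[[nm]])
    meta[[nm]] <- "history_onehot"
  }
  X <- do.call(cbind, lapply(cols, as.numeric))
  colnames(X) <- names(cols)
  rownames(X) <- table$episode_id
  list(
    X = X,
    maps = maps,
    column_meta = data.frame(name = names(cols),
                             origin = unlist(meta, use.names = FALSE)),
    new_category_events = if (length(events))
      do.call(rbind, c(events, list(make.row.names = FALSE)))
    else data.frame(feature = character(), level = character(), n = numeric())
  )
}

#' Split an episode table temporally into train / pre / during cohorts
#'
#' Intervals are half-open `[start, boundary)`: a record timestamped exactly
#' at a boundary joins the later period. Membership depends only on the
#' timestamp, never on row order.
#'
#' @param table an episode table.
#' @param boundary_1,boundary_2 datetimes (or anything `as.POSIXct` accepts),
#'   `boundary_1 < boundary_2`.
#' @return named list of three episode tables `train`, `test_pre`,
#'   `test_during`, each with a `cohort` column set.
#' @export
temporal_split <- function(table, boundary_1, boundary_2) {
  b1 <- as.POSIXct(boundary_1, tz = "UTC")
  b2 <- as.POSIXct(boundary_2, tz = "UTC")
  stop_if(is.na(b1) || is.na(b2), "unparseable boundary")
  stop_if(b1 >= b2, "boundary_1 must precede boundary_2")
  ts <- table$timestamp
  stop_if(anyNA(ts), "unparseable timestamps")
  cohort <- ifelse(ts < b1, "train", ifelse(ts < b2, "test_pre", "test_during"))
  out <- lapply(c(train = "train", test_pre = "test_pre",
                  test_during = "test_during"),
                function(cc) {
                  sub <- table[cohort == cc, , drop = FALSE]
                  sub$cohort <- cc
                  rownames(sub) <- NULL
                  sub
                })
  out
}

#' Serialise / load target-encoding maps as JSON
#'
#' @param maps named list of `target_encoding_map`s.
#' @param path file path.
#' @return `read_encoding_maps` returns the maps; `write_encoding_maps`
#'   returns `path` invisibly.
#' @export
write_encoding_maps <- function(maps, path) {
  doc <- lapply(maps, function(mp)
    list(levels = as.list(mp$levels), prior = mp$prior, m = mp$m))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoding_maps
#' @export
read_encoding_maps <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(d) structure(
    list(levels = unlist(d$levels), prior = d$prior, m = d$m),
    class = "target_encoding_map"))
}
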