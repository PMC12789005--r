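# Canonical survey dialect: UTF-8 delimiter-separated text, one row per
# respondent, header row, demographic columns followed by one column per
# question. Answer cells hold an integer category code 1..K, the literal
# string "DK" for an "I don't know" answer (only where the question offers
# one), or an empty cell for item non-response. In memory DK is stored as the
# integer sentinel 0L and non-response as NA.

DEMOGRAPHIC_COLS <- c("respondent_id", "country", "location", "sex", "age",
                      "politics")
LOCATION_LEVELS <- c("rural", "urban")
SEX_LEVELS <- c("female", "male")
POLITICS_LEVELS <- c("extreme_left", "left", "centre", "right",
                     "extreme_right", "missing")

#' Sentinel integer used for "I don't know" answers in memory
#'
#' Ordinal categories are coded `1..K`; the DK answer is kept outside the
#' ordinal scale as the sentinel `0L`. Item non-response is `NA`.
#' @export
dk_sentinel <- function() 0L

#' Describe one survey question
#'
#' @param question_id Short identifier, used as the dataset column name.
#' @param K Number of ordinal categories (>= 3).
#' @param labels Ordered category labels, most negative first, length K.
#' @param dk_label Label of the "I don't know" option, or `NULL` when the
#'   question has no DK option.
#' @return Object of class `question_spec`.
#' @export
question_spec <- function(question_id, K, labels = NULL, dk_label = NULL) {
  K <- check_K(K)
  if (is.null(labels)) labels <- paste0("cat", seq_len(K))
  if (length(labels) != K) {
    stop("question '", question_id, "': need ", K, " category labels",
         call. = FALSE)
  }
  structure(list(question_id = as.character(question_id), K = K,
                 labels = as.character(labels),
                 has_dont_know = !is.null(dk_label),
                 dk_label = if (is.null(dk_label)) NULL else as.character(dk_label)),
            class = "question_spec")
}

#' Bundle question specifications into a survey schema
#'
#' @param ... [question_spec()] objects (or a single list of them).
#' @return Object of class `survey_schema`: a named list keyed by question id.
#' @export
survey_schema <- function(...) {
  qs <- list(...)
  if (length(qs) == 1L && !inherits(qs[[1L]], "question_spec")) qs <- qs[[1L]]
  if (!length(qs) || !all(vapply(qs, inherits, TRUE, "question_spec"))) {
    stop("survey_schema() takes one or more question_spec objects", call. = FALSE)
  }
  ids <- vapply(qs, `[[`, "", "question_id")
  if (anyDuplicated(ids)) stop("duplicate question ids in schema", call. = FALSE)
  structure(stats::setNames(qs, ids), class = "survey_schema")
}

#' Read or write a survey schema as a YAML config file
#'
#' The file holds a list of questions, each with `question_id`, `K`, `labels`
#' and optionally `dk_label`.
#' @param path File path.
#' @return [read_schema()] returns a `survey_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  survey_schema(lapply(raw$questions, function(q) {
    question_spec(q$question_id, q$K, q$labels, q$dk_label)
  }))
}

#' @rdname read_schema
#' @param schema A `survey_schema`.
#' @export
write_schema <- function(schema, path) {
  qs <- lapply(unclass(schema), function(q) {
    out <- list(question_id = q$question_id, K = q$K, labels = q$labels)
    if (q$has_dont_know) out$dk_label <- q$dk_label
    out
  })
  yaml::write_yaml(list(questions = unname(qs)), path)
  invisible(path)
}

#' Read a respondent-level survey table
#'
#' Reads the canonical survey dialect (see package vignette), validates every
#' row against the schema and returns the dataset. Validation failures are
#' collected and reported together in the error message, naming row and
#' column; no row is silently dropped.
#'
#' @param path Path to the delimiter-separated survey file.
#' @param schema A [survey_schema()].
#' @param col_map Optional named character vector mapping file column names to
#'   canonical names (`c(old = "canonical", ...)`), for deposits whose headers
#'   differ from the canonical dialect.
#' @param sep Field delimiter (default comma).
#' @return Object of class `survey_dataset`: a data.frame with the demographic
#'   columns and one integer answer column per question (DK as 0L, missing as
#'   NA), carrying the schema as an attribute.
#' @export
read_survey <- function(path, schema, col_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  if (!inherits(schema, "survey_schema")) {
    stop("schema must be a survey_schema", call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    hit <- names(raw) %in% names(col_map)
    names(raw)[hit] <- unname(col_map[names(raw)[hit]])
  }
  qids <- names(schema)
  missing_cols <- setdiff(c(DEMOGRAPHIC_COLS, qids), names(raw))
  if (length(missing_cols)) {
    stop("survey file is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  note <- function(row, col, what) {
    problems <<- c(problems, paste0("row ", row, ", column '", col, "': ", what))
  }

  n <- nrow(raw)
  id <- trimws(raw$respondent_id)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    problems <- c(problems, paste0("duplicate respondent_id: ",
                                   paste(dup, collapse = ", ")))
  }
  check_level <- function(col, levels) {
    v <- trimws(raw[[col]])
    bad <- which(!v %in% levels)
    for (i in bad) note(i, col, paste0("'", v[i], "' not one of ",
                                       paste(levels, collapse = "/")))
    v
  }
  country <- toupper(trimws(raw$country))
  bad <- which(!grepl("^[A-Z]{2}$", country))
  for (i in bad) note(i, "country", paste0("'", country[i],
                                           "' is not a two-letter code"))
  location <- check_level("location", LOCATION_LEVELS)
  sex <- check_level("sex", SEX_LEVELS)
  politics <- trimws(raw$politics)
  politics[politics == ""] <- "missing"
  bad <- which(!politics %in% POLITICS_LEVELS)
  for (i in bad) note(i, "politics", paste0("'", politics[i], "' not one of ",
                                            paste(POLITICS_LEVELS, collapse = "/")))
  age <- suppressWarnings(as.integer(trimws(raw$age)))
  bad <- which(is.na(age) | age <= 0)
  for (i in bad) note(i, "age", paste0("'", raw$age[i],
                                       "' is not a positive integer"))

  ans <- lapply(qids, function(qid) {
    q <- schema[[qid]]
    v <- trimws(raw[[qid]])
    out <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (v[i] == "") next
      if (v[i] == "DK") {
        if (!q$has_dont_know) {
          note(i, qid, "DK answer on a question without a don't-know option")
        } else out[i] <- dk_sentinel()
        next
      }
      code <- suppressWarnings(as.integer(v[i]))
      if (is.na(code) || code < 1L || code > q$K ||
          as.character(code) != v[i]) {
        note(i, qid, paste0("unknown answer code '", v[i],
                            "' (expected 1..", q$K,
                            if (q$has_dont_know) ", DK" else "",
                            " or empty)"))
      } else out[i] <- code
    }
    out
  })
  if (length(problems)) {
    stop("survey validation failed (", length(problems), " problem",
         if (length(problems) > 1L) "s", "):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df <- data.frame(respondent_id = id, country = country, location = location,
                   sex = sex, age = age, politics = politics,
                   stringsAsFactors = FALSE)
  for (j in seq_along(qids)) df[[qids[j]]] <- ans[[j]]
  structure(df, schema = schema, class = c("survey_dataset", "data.frame"))
}

#' Write a survey dataset in the canonical dialect
#'
#' Inverse of [read_survey()]: DK sentinels become the literal `DK`, missing
#' answers become empty cells. Reading a canonical file and writing it back
#' reproduces it byte for byte.
#'
#' @param dataset A `survey_dataset`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_survey <- function(dataset, path, sep = ",") {
  schema <- attr(dataset, "schema")
  out <- as.data.frame(dataset)[, c(DEMOGRAPHIC_COLS, names(schema))]
  for (qid in names(schema)) {
    v <- out[[qid]]
    s <- ifelse(is.na(v), "", ifelse(v == dk_sentinel(), "DK", as.character(v)))
    out[[qid]] <- s
  }
  out$politics <- ifelse(out$politics == "missing", "", out$politics)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read the country metadata table
#'
#' One row per country with its rural population proportion (used to weight
#' rural and urban posterior estimates into country-level estimates) and,
#' optionally, the country median age.
#'
#' @param path Delimiter-separated file with columns `country`,
#'   `rural_proportion` and optionally `median_age`.
#' @param sep Field delimiter.
#' @return Data frame of class `country_meta` keyed by country code.
#' @export
read_country_meta <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("country", "rural_proportion")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("country metadata is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  country <- toupper(trimws(raw$country))
  if (anyDuplicated(country)) {
    stop("duplicate country rows in metadata: ",
         paste(unique(country[duplicated(country)]), collapse = ", "),
         call. = FALSE)
  }
  wr <- suppressWarnings(as.numeric(raw$rural_proportion))
  bad <- which(is.na(wr) | wr < 0 | wr > 1)
  if (length(bad)) {
    stop("rural_proportion outside [0, 1] for: ",
         paste(country[bad], collapse = ", "), call. = FALSE)
  }
  median_age <- if ("median_age" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$median_age))
  } else rep(NA_real_, length(country))
  structure(data.frame(country = country, rural_proportion = wr,
                       median_age = median_age, stringsAsFactors = FALSE),
            class = c("country_meta", "data.frame"))
}

#' Encode one question's answers for a stratum
#'
#' Extracts the ordinal codes and the DK count for the selected country and
#' rural/urban group. Item non-response is excluded (and counted); DK answers
#' are counted but excluded from the ordinal codes; `n_total` is ordinal plus
#' DK. A stratum with `n_total == 0` is returned as an explicit empty-stratum
#' object that the fitting functions refuse.
#'
#' @param dataset A `survey_dataset`.
#' @param question_id Question to encode.
#' @param country Two-letter country code, or `NULL` for all countries.
#' @param group `"rural"`, `"urban"` or `"all"`.
#' @return Object of class `encoded_responses` with fields `codes`,
#'   `dk_count`, `n_total`, `n_missing`, `K`, `has_dont_know`, `question_id`,
#'   `country`, `group`.
#' @export
encode_responses <- function(dataset, question_id, country = NULL,
                             group = c("all", "rural", "urban")) {
  group <- match.arg(group)
  schema <- attr(dataset, "schema")
  if (is.null(schema) || !question_id %in% names(schema)) {
    stop("question '", question_id, "' is not in the dataset schema",
         call. = FALSE)
  }
  q <- schema[[question_id]]
  keep <- rep(TRUE, nrow(dataset))
  if (!is.null(country)) keep <- keep & dataset$country == country
  if (group != "all") keep <- keep & dataset$location == group
  v <- dataset[[question_id]][keep]
  new_encoded(codes = v[!is.na(v) & v != dk_sentinel()],
              dk_count = sum(!is.na(v) & v == dk_sentinel()),
              n_missing = sum(is.na(v)),
              K = q$K, has_dont_know = q$has_dont_know,
              question_id = question_id,
              country = if (is.null(country)) "all" else country,
              group = group, category_labels = q$labels,
              dk_label = q$dk_label)
}

#' Construct an encoded response vector directly
#'
#' Builds the `encoded_responses` container from raw ordinal codes and a DK
#' count, for workflows that start from pre-tabulated answers rather than a
#' survey file.
#'
#' @param codes Integer vector of ordinal answers in `1..K`.
#' @param dk_count Number of "I don't know" answers.
#' @param K Number of ordinal categories.
#' @param has_dont_know Whether the question offers a DK option.
#' @param question_id,country,group Provenance labels.
#' @return An `encoded_responses` object.
#' @export
encoded_responses <- function(codes, dk_count = 0L, K,
                              has_dont_know = dk_count > 0L,
                              question_id = "q", country = "all",
                              group = "all") {
  codes <- as.integer(codes)
  if (length(codes) && (min(codes) < 1L || max(codes) > K)) {
    stop("ordinal codes must lie in 1..K", call. = FALSE)
  }
  if (dk_count > 0L && !has_dont_know) {
    stop("dk_count > 0 requires has_dont_know = TRUE", call. = FALSE)
  }
  new_encoded(codes, dk_count, 0L, K, has_dont_know, question_id, country,
              group)
}

new_encoded <- function(codes, dk_count, n_missing, K, has_dont_know,
                        question_id = "q", country = "all", group = "all",
                        category_labels = NULL, dk_label = NULL) {
  structure(list(codes = as.integer(codes), dk_count = as.integer(dk_count),
                 n_total = length(codes) + as.integer(dk_count),
                 n_missing = as.integer(n_missing), K = check_K(K),
                 has_dont_know = isTRUE(has_dont_know),
                 question_id = question_id, country = country, group = group,
                 category_labels = category_labels, dk_label = dk_label),
            class = "encoded_responses")
}

# Display labels for the (DK +) K categories, or NULL for generic defaults.
enc_labels <- function(encoded) {
  if (is.null(encoded$category_labels)) return(NULL)
  c(if (encoded$has_dont_know) encoded$dk_label %||% "DK",
    encoded$category_labels)
}

is_empty_stratum <- function(encoded) encoded$n_total == 0L

#' @export
print.encoded_responses <- function(x, ...) {
  cat("Encoded responses: question '", x$question_id, "', country ",
      x$country, ", group ", x$group, "\n", sep = "")
  cat("  K = ", x$K, "; n_total = ", x$n_total, " (", length(x$codes),
      " ordinal + ", x$dk_count, " DK); ", x$n_missing,
      " missing excluded\n", sep = "")
  if (x$n_total > 0L) {
    cat("  category counts:",
        paste(encoded_counts(x), collapse = " "), "\n")
  } else cat("  [empty stratum]\n")
  invisible(x)
}
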