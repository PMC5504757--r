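#' Default frequency tables for the synthetic person-record generator
#'
#' Returns the bundled synthetic value tables (given names, surnames,
#' suburbs, street names, street types, postcodes) together with
#' programmatically built tables for sex and date-of-birth components. All
#' name/place lists are synthetic — assembled from syllables with a
#' shifted-Zipf rank-frequency law — so that value frequencies are skewed the
#' way real population identifiers are (a handful of very common surnames, a
#' long tail of rare ones) without shipping any real person data.
#'
#' Each table is a `data.frame` with columns `value` and `weight`; weights
#' are non-negative and sum to one.
#'
#' @return named list of frequency tables for the fields
#'   `first_name`, `middle_name`, `last_name`, `sex`, `dob_year`,
#'   `dob_month`, `dob_day`, `suburb`, `postcode`, `street_name`,
#'   `street_type`.
#' @export
default_frequency_tables <- function() {
  read_tab <- function(file) {
    path <- system.file("extdata", file, package = "pprlink", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric"))
    df$weight <- df$weight / sum(df$weight)
    df
  }
  given <- read_tab("synthetic_given_names.csv")
  years <- 1920:2009
  # mildly increasing weight toward recent birth years (younger cohorts are
  # larger in most administrative collections)
  wy <- seq(0.6, 1.4, length.out = length(years))
  list(
    first_name = given,
    middle_name = given,
    last_name = read_tab("synthetic_surnames.csv"),
    sex = data.frame(value = c("M", "F"), weight = c(0.5, 0.5)),
    dob_year = data.frame(value = as.character(years), weight = wy / sum(wy)),
    dob_month = data.frame(value = as.character(1:12), weight = rep(1 / 12, 12)),
    dob_day = data.frame(value = as.character(1:31), weight = rep(1 / 31, 31)),
    suburb = read_tab("synthetic_suburbs.csv"),
    postcode = read_tab("synthetic_postcodes.csv"),
    street_name = read_tab("synthetic_street_names.csv"),
    street_type = data.frame(
      value = c("Street", "Road", "Avenue", "Way", "Drive", "Court", "Place",
                "Crescent", "Lane", "Terrace", "Close", "Parade"),
      weight = c(28, 20, 12, 8, 8, 6, 5, 4, 3, 3, 2, 1) / 100
    )
  )
}

#' Default distribution of records per individual
#'
#' Truncated geometric distribution: `P(k) proportional to p (1-p)^(k-1)` for
#' `k = 1, ..., max_k`. With the defaults (`p = 0.4`, `max_k = 10`) an
#' individual has on average about 2.5 records, emulating the multi-record
#' structure of hospital admission collections.
#'
#' @param p geometric success probability in (0, 1).
#' @param max_k largest number of records one individual may have.
#' @return named numeric vector; names are the duplicate counts `k`,
#'   values are probabilities summing to one.
#' @export
default_duplicate_distribution <- function(p = 0.4, max_k = 10) {
  stopifnot(p > 0, p < 1, max_k >= 1)
  w <- p * (1 - p)^(seq_len(max_k) - 1)
  stats::setNames(w / sum(w), as.character(seq_len(max_k)))
}

#' Configuration for the master-dataset generator
#'
#' @param n_records target number of records. Generation draws whole
#'   individuals until the target is reached, so the output may exceed the
#'   target by at most one individual's record count.
#' @param duplicate_distribution named numeric vector mapping duplicate count
#'   `k` (>= 1) to its probability; must sum to one (tolerance 1e-9).
#' @param frequency_tables named list of `data.frame(value, weight)` tables,
#'   as produced by [default_frequency_tables()].
#' @param seed integer seed; generation is fully deterministic given the
#'   configuration.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_records,
                             duplicate_distribution = default_duplicate_distribution(),
                             frequency_tables = default_frequency_tables(),
                             seed = 1L) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1) {
    stop("`n_records` must be a positive integer", call. = FALSE)
  }
  dd <- duplicate_distribution
  if (length(dd) == 0 || is.null(names(dd))) {
    stop("`duplicate_distribution` must be a named numeric vector", call. = FALSE)
  }
  k <- suppressWarnings(as.integer(names(dd)))
  if (anyNA(k) || any(k < 1)) {
    stop("duplicate counts must be integers >= 1", call. = FALSE)
  }
  if (any(dd < 0) || abs(sum(dd) - 1) > 1e-9) {
    stop("`duplicate_distribution` probabilities must be non-negative and sum to 1",
      call. = FALSE
    )
  }
  if (sum(dd[k >= 1]) <= 0) {
    stop("`duplicate_distribution` is degenerate (no mass on k >= 1)", call. = FALSE)
  }
  for (nm in names(frequency_tables)) {
    tab <- frequency_tables[[nm]]
    if (!is.data.frame(tab) || nrow(tab) == 0 ||
      !all(c("value", "weight") %in% names(tab))) {
      stop(sprintf("frequency table '%s' must be a non-empty data.frame with columns value, weight", nm),
        call. = FALSE
      )
    }
    if (any(tab$weight < 0) || abs(sum(tab$weight) - 1) > 1e-9) {
      stop(sprintf("frequency table '%s' weights must be non-negative and sum to 1", nm),
        call. = FALSE
      )
    }
  }
  required <- c(
    "first_name", "middle_name", "last_name", "sex", "dob_year", "dob_month",
    "dob_day", "suburb", "postcode", "street_name", "street_type"
  )
  missing_tabs <- setdiff(required, names(frequency_tables))
  if (length(missing_tabs)) {
    stop("missing frequency tables: ", paste(missing_tabs, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      n_records = n_records,
      duplicate_distribution = dd,
      frequency_tables = frequency_tables,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  target records:", x$n_records, "\n")
  cat("  duplicate distribution: k =", paste(names(x$duplicate_distribution), collapse = ","),
      "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

draw_values <- function(tab, n) {
  tab$value[sample.int(nrow(tab), n, replace = TRUE, prob = tab$weight)]
}

#' Generate an error-free master dataset with known duplicate structure
#'
#' Draws individuals (entities) with a configurable number of records each,
#' assigns every identifying field from a frequency table, and replicates the
#' values exactly across an individual's records: the master dataset contains
#' no missing values and no errors, so all records of one entity are
#' field-level copies distinguished only by `record_id`.
#'
#' @param config a [generator_config()].
#' @return a `data.frame` with columns `record_id`, `entity_id`, and the ten
#'   identifying fields; the truth mapping is the (`record_id`, `entity_id`)
#'   pair of columns (see [truth_from_dataset()]).
#' @export
generate_master <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  ft <- config$frequency_tables
  with_seed(config$seed, {
    dd <- config$duplicate_distribution
    kvals <- as.integer(names(dd))
    mean_k <- sum(kvals * dd)
    # draw duplicate counts until the record target is reached
    ks <- integer(0)
    total <- 0L
    while (total < config$n_records) {
      need <- max(16L, ceiling((config$n_records - total) / mean_k))
      batch <- kvals[sample.int(length(kvals), need, replace = TRUE, prob = dd)]
      keep <- cumsum(batch) + total
      cut <- which(keep >= config$n_records)
      if (length(cut)) batch <- batch[seq_len(cut[1])]
      ks <- c(ks, batch)
      total <- total + sum(batch)
    }
    ne <- length(ks)
    ent <- data.frame(
      entity_id = sprintf("E%07d", seq_len(ne)),
      first_name = draw_values(ft$first_name, ne),
      middle_name = draw_values(ft$middle_name, ne),
      last_name = draw_values(ft$last_name, ne),
      sex = draw_values(ft$sex, ne),
      dob_year = draw_values(ft$dob_year, ne),
      dob_month = draw_values(ft$dob_month, ne),
      dob_day = draw_values(ft$dob_day, ne),
      address = paste(
        sample.int(250, ne, replace = TRUE),
        draw_values(ft$street_name, ne),
        draw_values(ft$street_type, ne)
      ),
      suburb = draw_values(ft$suburb, ne),
      postcode = draw_values(ft$postcode, ne),
      stringsAsFactors = FALSE
    )
    rows <- rep.int(seq_len(ne), ks)
    rows <- rows[sample.int(length(rows))] # interleave entities
    out <- ent[rows, , drop = FALSE]
    out$record_id <- sprintf("R%08d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out[, PERSON_COLUMNS]
  })
}

#' Extract the truth mapping from a generated dataset
#'
#' @param dataset a dataset with `record_id` and `entity_id` columns.
#' @return `data.frame(record_id, entity_id)`.
#' @export
truth_from_dataset <- function(dataset) {
  data.frame(
    record_id = dataset$record_id, entity_id = dataset$entity_id,
    stringsAsFactors = FALSE
  )
}

#' Configuration for dataset corruption
#'
#' @param error_rate fraction in `[0, 0.5]`. Each (record, field) cell is
#'   independently set to missing with this probability; a further disjoint
#'   fraction of cells (same rate) is corrupted by one of the error
#'   operators.
#' @param operator_mix named probabilities over the operators
#'   `typo`, `misspelling`, `truncation`, `replacement`; must sum to one.
#' @param seed integer seed.
#' @return an object of class `corruption_config`.
#' @export
corruption_config <- function(error_rate,
                              operator_mix = c(
                                typo = 0.25, misspelling = 0.25,
                                truncation = 0.25, replacement = 0.25
                              ),
                              seed = 1L) {
  if (!is.numeric(error_rate) || length(error_rate) != 1 ||
    is.na(error_rate) || error_rate < 0 || error_rate > 0.5) {
    stop("`error_rate` must be a single number in [0, 0.5]", call. = FALSE)
  }
  ops <- c("typo", "misspelling", "truncation", "replacement")
  if (!setequal(names(operator_mix), ops)) {
    stop("`operator_mix` must be named over ", paste(ops, collapse = ", "),
      call. = FALSE
    )
  }
  operator_mix <- operator_mix[ops]
  if (any(operator_mix < 0) || abs(sum(operator_mix) - 1) > 1e-9) {
    stop("`operator_mix` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(
      error_rate = error_rate, operator_mix = operator_mix,
      seed = as.integer(seed)
    ),
    class = "corruption_config"
  )
}

# keyboard-adjacency map for the typo operator (QWERTY layout, letters and
# digits)
keyboard_neighbours <- local({
  rows <- c("1234567890", "QWERTYUIOP", "ASDFGHJKL", "ZXCVBNM")
  adj <- list()
  for (r in seq_along(rows)) {
    chars <- strsplit(rows[r], "")[[1]]
    for (i in seq_along(chars)) {
      nb <- character(0)
      if (i > 1) nb <- c(nb, chars[i - 1])
      if (i < length(chars)) nb <- c(nb, chars[i + 1])
      for (r2 in c(r - 1, r + 1)) {
        if (r2 >= 1 && r2 <= length(rows)) {
          chars2 <- strsplit(rows[r2], "")[[1]]
          if (i <= length(chars2)) nb <- c(nb, chars2[i])
        }
      }
      adj[[chars[i]]] <- nb
    }
  }
  adj
})

corrupt_text_one <- function(value, op, tab) {
  n <- nchar(value)
  if (op == "truncation" && n < 2) op <- "replacement"
  switch(op,
    typo = {
      pos <- sample.int(n, 1)
      ch <- toupper(substr(value, pos, pos))
      nb <- keyboard_neighbours[[ch]]
      repl <- if (is.null(nb)) sample(LETTERS, 1) else sample(nb, 1)
      paste0(substr(value, 1, pos - 1), repl, substr(value, pos + 1, n))
    },
    misspelling = {
      kind <- sample(c("insert", "delete", "substitute"), 1)
      if (kind == "delete" && n < 2) kind <- "insert"
      pos <- sample.int(n, 1)
      ch <- sample(LETTERS, 1)
      switch(kind,
        insert = paste0(substr(value, 1, pos), ch, substr(value, pos + 1, n)),
        delete = paste0(substr(value, 1, pos - 1), substr(value, pos + 1, n)),
        substitute = paste0(substr(value, 1, pos - 1), ch, substr(value, pos + 1, n))
      )
    },
    truncation = {
      drop <- sample.int(min(3L, n - 1L), 1)
      substr(value, 1, n - drop)
    },
    replacement = draw_values(tab, 1)
  )
}

corrupt_field_values <- function(values, field, ops, ft) {
  n <- length(values)
  out <- values
  for (i in seq_len(n)) {
    v <- values[i]
    if (is.na(v) || v == "") next
    out[i] <- switch(field,
      sex = if (v == "M") "F" else "M",
      dob_month = as.character(sample(setdiff(1:12, as.integer(v)), 1)),
      dob_day = as.character(sample(setdiff(1:31, as.integer(v)), 1)),
      dob_year = {
        # substitute one digit, keeping a 4-digit parseable year
        pos <- sample.int(4, 1)
        d <- sample(setdiff(0:9, as.integer(substr(v, pos, pos))), 1)
        if (pos == 1 && d == 0) d <- sample(1:9, 1)
        paste0(substr(v, 1, pos - 1), d, substr(v, pos + 1, 4))
      },
      address = {
        op <- ops[i]
        if (op == "replacement") {
          paste(
            sample.int(250, 1), draw_values(ft$street_name, 1),
            draw_values(ft$street_type, 1)
          )
        } else {
          corrupt_text_one(v, op, ft$street_name)
        }
      },
      corrupt_text_one(v, ops[i], ft[[field]])
    )
  }
  out
}

#' Corrupt a dataset with missingness and value errors at a stated rate
#'
#' For every (record, linkage-field) cell two independent Bernoulli draws at
#' `error_rate` decide whether the cell is set to missing and whether it is
#' corrupted; missingness takes precedence, so the corrupted cells are a
#' disjoint further fraction, and one record can have several fields
#' affected. Corruption applies one operator drawn from the configured mix:
#' keyboard-adjacent typo, single-edit misspelling, truncation of 1-3
#' trailing characters, or replacement by a fresh draw from the field's
#' frequency table. Sex is flipped and date components are redrawn/digit-
#' substituted within valid ranges so values stay parseable. `record_id` and
#' `entity_id` are never altered.
#'
#' @param dataset a person-record `data.frame` (see [generate_master()]).
#' @param config a [corruption_config()].
#' @param frequency_tables tables used by the replacement operator; defaults
#'   to the bundled ones.
#' @return the corrupted dataset, same rows and columns, with `NA` marking
#'   missing values.
#' @export
corrupt_dataset <- function(dataset, config,
                            frequency_tables = default_frequency_tables()) {
  stopifnot(inherits(config, "corruption_config"))
  if (nrow(dataset) == 0) stop("`dataset` must be non-empty", call. = FALSE)
  if (config$error_rate == 0) {
    return(dataset)
  }
  out <- dataset
  with_seed(config$seed, {
    n <- nrow(dataset)
    for (field in LINKAGE_FIELDS) {
      miss <- runif(n) < config$error_rate
      corr <- !miss & (runif(n) < config$error_rate)
      vals <- as.character(out[[field]])
      if (any(corr)) {
        idx <- which(corr)
        ops <- sample(names(config$operator_mix), length(idx),
          replace = TRUE, prob = config$operator_mix
        )
        vals[idx] <- corrupt_field_values(vals[idx], field, ops, frequency_tables)
      }
      vals[miss] <- NA_character_
      out[[field]] <- vals
    }
  })
  out
}

#' Read and write person-record CSV files
#'
#' Datasets are exchanged as UTF-8 CSV with a header row and the fixed column
#' order `record_id, entity_id, first_name, middle_name, last_name, sex,
#' dob_year, dob_month, dob_day, address, suburb, postcode`; an empty cell
#' means missing. Truth files carry `record_id, entity_id` only.
#'
#' @param dataset,truth data frames to write.
#' @param path file path.
#' @return `read_person_csv()` and `read_truth_csv()` return data frames;
#'   the writers return `path` invisibly.
#' @name person_csv
#' @export
write_person_csv <- function(dataset, path) {
  if (!("entity_id" %in% names(dataset))) dataset$entity_id <- ""
  stopifnot(all(PERSON_COLUMNS %in% names(dataset)))
  out <- dataset[, PERSON_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname person_csv
#' @export
read_person_csv <- function(path) {
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE, colClasses = "character",
    fileEncoding = "UTF-8"
  )
  missing_cols <- setdiff(setdiff(PERSON_COLUMNS, "entity_id"), names(df))
  if (length(missing_cols)) {
    stop("person CSV lacks columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (f in LINKAGE_FIELDS) df[[f]][!is.na(df[[f]]) & df[[f]] == ""] <- NA_character_
  df
}

#' @rdname person_csv
#' @export
write_truth_csv <- function(truth, path) {
  stopifnot(all(c("record_id", "entity_id") %in% names(truth)))
  utils::write.csv(truth[, c("record_id", "entity_id")], path,
    row.names = FALSE, na = "", quote = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' @rdname person_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
}
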