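# Item bank container and CSV serialization.
# Schema (one item per row): item_id, dimension, a, b, c.

BANK_COLUMNS <- c("item_id", "dimension", "a", "b", "c")

#' Construct an item bank
#'
#' An item bank is a data frame of 3PL item parameters with a between-item
#' loading structure: each item measures exactly one dimension.
#'
#' @param items Data frame with columns `item_id` (unique integer),
#'   `dimension` (1-based loaded dimension), `a` (> 0), `b`, `c` (in
#'   `[0, 1)`).
#' @param D Number of dimensions; defaults to `max(items$dimension)`.
#' @return An object of class `item_bank` (a data frame with attribute `D`).
#' @export
item_bank <- function(items, D = max(items$dimension)) {
  missing_cols <- setdiff(BANK_COLUMNS, names(items))
  if (length(missing_cols)) {
    stop("item bank lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  items <- as.data.frame(items)[BANK_COLUMNS]
  for (col in BANK_COLUMNS) {
    bad <- which(!is.finite(items[[col]]))
    if (length(bad)) {
      stop("non-numeric or missing `", col, "` in row ", bad[[1L]],
           call. = FALSE)
    }
  }
  dup <- which(duplicated(items$item_id))
  if (length(dup)) {
    stop("duplicate item_id ", items$item_id[dup[[1L]]], " in row ", dup[[1L]],
         call. = FALSE)
  }
  bad <- which(items$a <= 0)
  if (length(bad)) stop("a <= 0 in row ", bad[[1L]], call. = FALSE)
  bad <- which(items$c < 0 | items$c >= 1)
  if (length(bad)) stop("c outside [0, 1) in row ", bad[[1L]], call. = FALSE)
  bad <- which(items$dimension < 1 | items$dimension > D |
                 items$dimension != round(items$dimension))
  if (length(bad)) {
    stop("dimension outside 1..", D, " in row ", bad[[1L]], call. = FALSE)
  }
  if (!setequal(unique(items$dimension), seq_len(D))) {
    stop("every dimension 1..", D, " needs at least one item", call. = FALSE)
  }
  items$item_id <- as.integer(items$item_id)
  items$dimension <- as.integer(items$dimension)
  structure(items, D = as.integer(D),
            class = c("item_bank", "data.frame"))
}

as_item_bank <- function(x) {
  if (inherits(x, "item_bank")) x else item_bank(x)
}

#' @export
print.item_bank <- function(x, ...) {
  cat("<item_bank> ", nrow(x), " items, ", attr(x, "D"), " dimensions\n",
      sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

#' Generate a synthetic item bank
#'
#' Draws `items_per_dim` items for each of `D` dimensions with
#' `a ~ N(a_mean, a_sd^2)` (redrawn while nonpositive),
#' `b ~ U(b_range)` and `c ~ U(c_range)`, matching the stated simulation
#' design (300 items per dimension; `N(1, 0.25^2)`, `U(-3.6, 3.6)`,
#' `U(0, 0.3)`).  Uses the current RNG state.
#'
#' @param items_per_dim Items per dimension.
#' @param D Number of dimensions.
#' @param a_mean,a_sd Mean and SD of the discrimination distribution.
#' @param b_range,c_range Uniform ranges of difficulty and guessing.
#' @return An [item_bank()].
#' @export
generate_bank <- function(items_per_dim = 300L, D = 2L,
                          a_mean = 1, a_sd = 0.25,
                          b_range = c(-3.6, 3.6), c_range = c(0, 0.3)) {
  n <- items_per_dim * D
  a <- stats::rnorm(n, a_mean, a_sd)
  while (any(bad <- a <= 0)) a[bad] <- stats::rnorm(sum(bad), a_mean, a_sd)
  item_bank(data.frame(
    item_id = seq_len(n),
    dimension = rep(seq_len(D), each = items_per_dim),
    a = a,
    b = stats::runif(n, b_range[[1L]], b_range[[2L]]),
    c = stats::runif(n, c_range[[1L]], c_range[[2L]])
  ), D = D)
}

#' Read an item bank from CSV
#'
#' Expects the header `item_id, dimension, a, b, c`; numeric fields
#' round-trip at full double precision with [write_item_bank()].
#'
#' @param path Path to a CSV file.
#' @return An [item_bank()].
#' @export
read_item_bank <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("cannot parse item bank CSV `", path, "`: ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("cannot parse item bank CSV `", path, "`: ",
                               conditionMessage(w), call. = FALSE)
  )
  missing_cols <- setdiff(BANK_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("item bank CSV `", path, "` lacks header column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  item_bank(raw)
}

#' Write an item bank to CSV
#'
#' @param bank An [item_bank()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  bank <- as_item_bank(bank)
  out <- data.frame(
    item_id = bank$item_id,
    dimension = bank$dimension,
    a = sprintf("%.17g", bank$a),
    b = sprintf("%.17g", bank$b),
    c = sprintf("%.17g", bank$c)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
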