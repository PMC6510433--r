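# Data model, IO, cleaning and descriptive statistics for colour-naming
# response tables. A naming table holds per-chip response counts over a name
# vocabulary, built from long-format records (one row per response).

.normalize_names <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Build a naming table from long-format response records
#'
#' @param responses data frame with columns \code{subject}, \code{name},
#'   either \code{r,g,b} (sRGB in \eqn{[0,1]}) or \code{chip_id} plus a
#'   \code{chips} argument, and optionally \code{presentation_index}.
#' @param chips optional data frame of chip coordinates (columns
#'   \code{chip_id, r, g, b}) when \code{responses} carries only
#'   \code{chip_id}.
#' @param clean apply the cleaning rules (name normalization, variant map,
#'   repeat-presentation and single-subject-unique removal)? Default TRUE.
#' @param variant_map named character vector mapping spelling variants to
#'   canonical names, e.g. \code{c(gray = "grey")}.
#' @return list with elements \code{table} (a \code{"naming_table"}) and
#'   \code{report} (a \code{"cleaning_report"}).
#' @details Cleaning proceeds in order: names are lower-cased and
#'   whitespace-normalized; the variant map is applied; for each subject,
#'   later presentations of a chip already shown to that subject are dropped
#'   as repeats (they are retained separately for intra-subject agreement);
#'   finally every name whose uses all come from a single subject is dropped
#'   together with its records.
#' @export
naming_table <- function(responses, chips = NULL, clean = TRUE,
                         variant_map = NULL) {
  if (!is.data.frame(responses) || nrow(responses) == 0)
    stop("responses must be a non-empty data frame")
  if (!all(c("subject", "name") %in% names(responses)))
    stop("responses must have 'subject' and 'name' columns")
  if (!all(c("r", "g", "b") %in% names(responses))) {
    if (is.null(chips) || !("chip_id" %in% names(responses)))
      stop("responses need r,g,b columns or chip_id plus a chips table")
    m <- match(responses$chip_id, chips$chip_id)
    if (anyNA(m)) stop("chip_id values missing from the chips table")
    responses$r <- chips$r[m]; responses$g <- chips$g[m]
    responses$b <- chips$b[m]
  }
  bad <- which(!is.finite(responses$r) | !is.finite(responses$g) |
               !is.finite(responses$b) |
               responses$r < 0 | responses$r > 1 |
               responses$g < 0 | responses$g > 1 |
               responses$b < 0 | responses$b > 1 |
               is.na(responses$name) | trimws(responses$name) == "")
  if (length(bad))
    stop("malformed rows (bad coordinates or empty name) at lines: ",
         paste(utils::head(bad, 20), collapse = ", "))

  n_input <- nrow(responses)
  n_repeat <- 0L; n_unique <- 0L; dropped_names <- character()
  repeat_pairs <- NULL

  if (clean) {
    responses$name <- .normalize_names(responses$name)
    if (!is.null(variant_map)) {
      vm_from <- .normalize_names(names(variant_map))
      vm_to <- .normalize_names(unname(variant_map))
      m <- match(responses$name, vm_from)
      hit <- !is.na(m)
      responses$name[hit] <- vm_to[m[hit]]
    }
    # repeat presentations are only identifiable when the presentation
    # order is recorded: per subject, keep the first presentation of each
    # chip, drop later ones; record (first, repeat) name pairs for the
    # intra-subject agreement statistic
    if ("presentation_index" %in% names(responses)) {
    key <- paste(responses$subject, responses$r, responses$g, responses$b,
                 sep = "\r")
    ord <- order(responses$subject, responses$presentation_index)
    first_of <- ord[!duplicated(key[ord])]
    is_rep <- !(seq_len(nrow(responses)) %in% first_of)
    if (any(is_rep)) {
      rep_rows <- which(is_rep)
      m <- match(key[rep_rows], key[first_of])
      repeat_pairs <- data.frame(
        subject = responses$subject[rep_rows],
        first = responses$name[first_of][m],
        second = responses$name[rep_rows])
      n_repeat <- length(rep_rows)
      responses <- responses[!is_rep, , drop = FALSE]
    }
    }
    # single-subject-unique names: all uses of the name come from 1 subject
    nsub <- tapply(responses$subject, responses$name,
                   function(s) length(unique(s)))
    uniq <- names(nsub)[nsub == 1]
    if (length(uniq)) {
      drop <- responses$name %in% uniq
      n_unique <- sum(drop)
      dropped_names <- uniq
      responses <- responses[!drop, , drop = FALSE]
    }
    if (nrow(responses) == 0)
      stop("cleaning removed every record")
  }

  chip_key <- paste(responses$r, responses$g, responses$b, sep = "\r")
  chip_levels <- unique(chip_key)
  chip_idx <- match(chip_key, chip_levels)
  first <- match(chip_levels, chip_key)
  chips_df <- data.frame(chip_id = seq_along(chip_levels),
                         r = responses$r[first], g = responses$g[first],
                         b = responses$b[first])
  vocab <- sort(unique(responses$name))
  counts <- table(factor(chip_idx, levels = seq_along(chip_levels)),
                  factor(responses$name, levels = vocab))
  counts <- matrix(as.integer(counts), nrow = length(chip_levels),
                   dimnames = list(NULL, vocab))
  tab <- structure(list(
    chips = chips_df,
    lab = .as_lab_matrix(srgb_to_lab(as.matrix(chips_df[, c("r", "g", "b")]))),
    vocabulary = vocab,
    counts = counts,
    responses = responses,
    repeat_pairs = repeat_pairs), class = "naming_table")
  report <- structure(list(
    variant_map = variant_map,
    n_input = n_input,
    n_repeat_dropped = n_repeat,
    n_unique_dropped = n_unique,
    n_retained = nrow(responses),
    dropped_names = dropped_names), class = "cleaning_report")
  list(table = tab, report = report)
}

#' Read a colour-naming response table from CSV/TSV
#'
#' Long format, one record per response; header required; columns
#' \code{subject}, \code{name}, and either \code{r,g,b} or \code{chip_id}
#' (with \code{chips_path} giving the chip list); optional
#' \code{presentation_index}.
#'
#' @param path file path; \code{.tsv}/\code{.tab} files are read as
#'   tab-separated, anything else as comma-separated.
#' @param variant_map named character vector of spelling variants.
#' @param chips_path optional path to a chip list (chip_id, r, g, b).
#' @inheritParams naming_table
#' @return list(table, report) as for [naming_table()].
#' @export
read_naming_table <- function(path, variant_map = NULL, chips_path = NULL,
                              clean = TRUE) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0) stop("empty table: ", path)
  chips <- if (!is.null(chips_path))
    utils::read.table(chips_path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE) else NULL
  naming_table(df, chips = chips, clean = clean, variant_map = variant_map)
}

#' @export
print.naming_table <- function(x, ...) {
  cat(sprintf("<naming_table: %d chips, %d names, %d responses>\n",
              nrow(x$chips), length(x$vocabulary), sum(x$counts)))
  invisible(x)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  input records:        %d\n", x$n_input))
  cat(sprintf("  repeat drops:         %d\n", x$n_repeat_dropped))
  cat(sprintf("  unique-name drops:    %d (%d names)\n",
              x$n_unique_dropped, length(x$dropped_names)))
  cat(sprintf("  retained:             %d\n", x$n_retained))
  invisible(x)
}

#' Global response rates
#'
#' The fraction of all responses accounted for by each name, ordered by
#' descending count with lexicographic tie-break.
#'
#' @param table a \code{"naming_table"}.
#' @return named numeric vector summing to 1.
#' @export
global_rates <- function(table) {
  counts <- colSums(table$counts)
  g <- counts / sum(counts)
  g[order(-counts, names(counts))]
}

#' Exponential fit to power-transformed global rates
#'
#' Applies the power transform \eqn{g^{q}} (default exponent 0.12) to the
#' global name rates and fits an exponential distribution by maximum
#' likelihood; the transformed rates of crowd-sourced naming data follow
#' this law closely, which motivates the \eqn{\lambda (k|\Sigma|)^{0.12}}
#' penalty used in model fitting.
#'
#' @param g vector of strictly positive rates (need not be normalized).
#' @param exponent power-transform exponent (default 0.12).
#' @return list with the transformed values, the fitted exponential
#'   \code{rate}, a Kolmogorov-Smirnov goodness-of-fit statistic and p-value,
#'   and a \code{degenerate} flag (all transformed values equal).
#' @export
rate_law_fit <- function(g, exponent = 0.12) {
  g <- as.numeric(g)
  if (length(g) < 3) stop("need at least 3 rates to fit the rate law")
  if (any(!is.finite(g)) || any(g <= 0))
    stop("rates must be strictly positive")
  x <- g^exponent
  degenerate <- stats::sd(x) < 1e-12 * mean(x)
  rate <- 1 / mean(x)
  ks <- if (degenerate) list(statistic = NA_real_, p.value = NA_real_)
        else suppressWarnings(stats::ks.test(x, "pexp", rate = rate))
  list(transformed = x, exponent = exponent, rate = rate,
       ks_statistic = unname(ks$statistic), ks_p_value = ks$p.value,
       degenerate = degenerate)
}

.entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Descriptive statistics of a naming table
#'
#' Entropies (bits) of the global and per-chip response distributions,
#' the mutual information between chips and names, and (when the metadata
#' allows) inter- and intra-subject agreement rates.
#'
#' @param table a \code{"naming_table"}.
#' @return list with \code{global_entropy}, \code{chip_entropies},
#'   \code{mean_chip_entropy}, \code{mutual_information},
#'   \code{conditional_entropy} (names given chip), and, if available,
#'   \code{inter_subject_agreement} and \code{intra_subject_agreement}.
#' @details The inter-subject agreement rate (probability that two distinct
#'   subjects give the exact same response to a random chip) is estimated by
#'   the unbiased per-chip pair-coincidence statistic
#'   \eqn{\sum_n r_n(r_n - 1) / (R(R-1))}, averaged over chips. Intra-subject
#'   agreement is the fraction of repeat-presentation pairs with equal
#'   responses.
#' @export
naming_statistics <- function(table) {
  counts <- table$counts
  total <- sum(counts)
  g <- colSums(counts) / total
  p_chip <- rowSums(counts) / total
  global_entropy <- .entropy_bits(g)
  chip_entropies <- apply(counts, 1, function(r) {
    R <- sum(r)
    if (R == 0) return(NA_real_)
    .entropy_bits(r / R)
  })
  cond <- sum(p_chip * ifelse(is.na(chip_entropies), 0, chip_entropies))
  mi <- global_entropy - cond
  out <- list(global_entropy = global_entropy,
              chip_entropies = chip_entropies,
              mean_chip_entropy = mean(chip_entropies, na.rm = TRUE),
              mutual_information = mi,
              conditional_entropy = cond)
  # inter-subject agreement needs subject metadata (>=2 responses per chip)
  if (!is.null(table$responses) && "subject" %in% names(table$responses)) {
    R <- rowSums(counts)
    ok <- R >= 2
    if (any(ok)) {
      coinc <- rowSums(counts * (counts - 1))[ok] / (R[ok] * (R[ok] - 1))
      out$inter_subject_agreement <- mean(coinc)
    }
  }
  if (!is.null(table$repeat_pairs) && nrow(table$repeat_pairs) > 0)
    out$intra_subject_agreement <-
      mean(table$repeat_pairs$first == table$repeat_pairs$second)
  out
}
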