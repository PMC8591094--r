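# Readers and writers for every external format the pipeline touches.
# Formats: expression TSV (header = sample ids, column 1 = gene symbol),
# 2-column class TSV, SIF / 2-column interaction TSV, clinical TSV, GMT.

#' Construct a validated expression matrix
#'
#' The core expression container: a numeric matrix of log2-scale intensities
#' with genes as rows and samples as columns, plus optional tumor/normal
#' class labels. All downstream modules (differential expression, scoring)
#' operate on this object.
#'
#' @param values Numeric matrix, rows = genes, columns = samples; dimnames
#'   must be set and unique, all values finite.
#' @param class_labels Optional named character vector mapping sample id to
#'   `"case"` or `"control"`. Names must be a subset of the sample ids.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `class_labels`.
#' @export
expression_matrix <- function(values, class_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stopf("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stopf("expression matrix contains non-finite values")
  if (!is.null(class_labels)) {
    if (is.null(names(class_labels)))
      stopf("class_labels must be named by sample id")
    bad <- setdiff(names(class_labels), colnames(values))
    if (length(bad))
      stopf("class labels for unknown samples: %s", paste(bad, collapse = ", "))
    if (!all(class_labels %in% c("case", "control")))
      stopf("class labels must be 'case' or 'control'")
    class_labels <- class_labels[colnames(values)[colnames(values) %in% names(class_labels)]]
  }
  structure(list(values = values, class_labels = class_labels),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$class_labels)) {
    tab <- table(x$class_labels)
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row holds the sample ids and
#' whose first column holds gene symbols. Values are assumed to already be
#' on the log2 scale (e.g. GC-RMA or level-3 array output); set
#' `linear_input = TRUE` to apply `log2(x + 1)` on load, which matters for
#' fold-change semantics downstream.
#'
#' Duplicate gene rows (multiple probes collapsing to one symbol) are
#' resolved deterministically by keeping the row with the highest mean
#' intensity; a warning reports how many rows were dropped.
#'
#' @param path Path to the expression TSV.
#' @param class_path Optional path to a 2-column TSV (sample, label) with
#'   labels `case`/`control`.
#' @param linear_input If `TRUE`, values are linear-scale and are
#'   log2(x+1)-transformed on load.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, class_path = NULL, linear_input = FALSE) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) < 2L) stopf("expression file '%s' has no data rows", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stopf("malformed header in '%s': need a gene column plus >=1 sample", path)
  sample_ids <- str_trim(header[-1])
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  genes <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(sample_ids))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(header))
      stopf("row %d of '%s' has %d fields, expected %d",
            i + 1L, path, length(r), length(header))
    genes[i] <- str_trim(r[1])
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stopf("non-numeric cell at gene '%s' (row %d), sample '%s': '%s'",
            genes[i], i + 1L, sample_ids[j], r[j + 1L])
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    keep <- collapse_duplicate_rows(genes, vals)
    warnf("%d duplicate gene rows collapsed (kept highest mean intensity)",
          length(genes) - length(keep))
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (linear_input) vals <- log2(vals + 1)
  dimnames(vals) <- list(genes, sample_ids)
  labels <- if (!is.null(class_path)) read_class_labels(class_path) else NULL
  expression_matrix(vals, labels)
}

# Index of rows to keep: per symbol, the row with the highest mean intensity
# (ties broken by first occurrence). Returned in original row order.
collapse_duplicate_rows <- function(genes, vals) {
  means <- rowMeans(vals)
  keep <- vapply(split(seq_along(genes), genes), function(idx) {
    idx[which.max(means[idx])]
  }, integer(1))
  sort(unname(keep))
}

read_class_labels <- function(path) {
  if (!file.exists(path)) stopf("class label file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) < 2L) stopf("class file '%s' must have 2 columns", path)
  # tolerate an optional header line
  if (identical(tolower(str_trim(df[1, 2])), "label")) df <- df[-1, , drop = FALSE]
  lab <- str_trim(as.character(df[[2]]))
  nm <- str_trim(as.character(df[[1]]))
  bad <- setdiff(unique(lab), c("case", "control"))
  if (length(bad))
    stopf("class file '%s': labels must be case/control, found: %s",
          path, paste(bad, collapse = ", "))
  stats::setNames(lab, nm)
}

#' Read a gene list (one symbol per line)
#'
#' Used for the copy-number-altered gene list. Symbols are whitespace-trimmed
#' and matched case-sensitively; no alias resolution is attempted.
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @param source_tag Free-text provenance tag attached to the result.
#' @return Character vector of unique symbols with attribute `source_tag`.
#' @export
read_gene_list <- function(path, source_tag = "CNA") {
  if (!file.exists(path)) stopf("gene list file not found: %s", path)
  sym <- str_trim(readLines(path))
  sym <- sym[nzchar(sym)]
  if (!length(sym)) stopf("gene list '%s' is empty", path)
  if (anyDuplicated(sym)) {
    warnf("gene list '%s': %d duplicate symbols dropped",
          path, sum(duplicated(sym)))
    sym <- unique(sym)
  }
  structure(sym, source_tag = source_tag)
}

#' Read an undirected interaction edge list
#'
#' Supports the Cytoscape SIF dialect (`A type B [C ...]`, whitespace- or
#' tab-delimited; one edge per target) and plain 2-column TSV. Edges are
#' undirected and deduplicated; self-interactions are dropped and counted.
#'
#' @param path Path to the interaction file.
#' @param dialect `"sif"` or `"tsv2"`.
#' @return A two-column character matrix of unique undirected edges
#'   (columns `from`, `to`), with attribute `n_self_dropped`.
#' @export
read_edge_list <- function(path, dialect = c("sif", "tsv2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("edge list file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(str_trim(lines))
  pairs <- list()
  for (i in which(keep)) {
    tok <- if (dialect == "sif") strsplit(str_trim(lines[i]), "\\s+")[[1]]
           else str_trim(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (dialect == "tsv2") {
      if (length(tok) < 2L)
        stopf("line %d of '%s': expected 2 columns, got %d", i, path, length(tok))
      pairs[[length(pairs) + 1L]] <- cbind(tok[1], tok[2])
    } else {
      if (length(tok) < 2L)
        stopf("line %d of '%s': SIF line needs source, type and >=1 target", i, path)
      if (length(tok) == 2L)
        stopf("line %d of '%s': SIF line has a type but no target", i, path)
      pairs[[length(pairs) + 1L]] <- cbind(tok[1], tok[-(1:2)])
    }
  }
  if (!length(pairs)) stopf("edge list '%s' contains no edges", path)
  m <- do.call(rbind, pairs)
  self <- m[, 1] == m[, 2]
  n_self <- sum(self)
  if (n_self) message(sprintf("dropped %d self-interaction(s)", n_self))
  m <- m[!self, , drop = FALSE]
  # canonical orientation then dedup -> order/orientation invariant
  canon <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  canon <- canon[!duplicated(paste(canon[, 1], canon[, 2], sep = "\r")), ,
                 drop = FALSE]
  canon <- canon[order(canon[, 1], canon[, 2]), , drop = FALSE]
  colnames(canon) <- c("from", "to")
  attr(canon, "n_self_dropped") <- n_self
  canon
}

#' Read a clinical table
#'
#' Expects a TSV with columns `sample`, `time`, `event`, `age`, `gender`,
#' `stage`, `lymphatic_invasion`. Continuous/multi-level fields are mapped
#' to the binary contrasts used throughout the survival module:
#' age to `>=50` vs `<50`, pathologic stage to `III-IV` vs `I-II`,
#' lymphatic invasion to `yes`/`no` (`unknown` becomes `NA`). Unrecognized
#' levels become missing values.
#'
#' @param path Path to the clinical TSV.
#' @return A `data.frame` with columns `sample`, `time`, `event`,
#'   `age_group`, `gender`, `stage_group`, `lymphatic_invasion`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  need <- c("sample", "time", "event", "age", "gender", "stage",
            "lymphatic_invasion")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("clinical file '%s' is missing columns: %s", path,
          paste(miss, collapse = ", "))
  clinical_table(
    sample = as.character(df$sample),
    time = as.numeric(df$time),
    event = as.numeric(df$event),
    age_group = encode_age(df$age),
    gender = encode_level(df$gender, c("female", "male")),
    stage_group = encode_stage(df$stage),
    lymphatic_invasion = encode_level(df$lymphatic_invasion, c("yes", "no"))
  )
}

#' Construct and validate a clinical table
#'
#' @param sample Sample identifiers (unique).
#' @param time Non-negative follow-up times.
#' @param event Event indicator, 1 = death/event, 0 = censored.
#' @param age_group `">=50"` or `"<50"` (or `NA`).
#' @param gender `"female"` or `"male"` (or `NA`).
#' @param stage_group `"III-IV"` or `"I-II"` (or `NA`).
#' @param lymphatic_invasion `"yes"` or `"no"` (or `NA`).
#' @return A validated `data.frame` of class `clinical_table`.
#' @export
clinical_table <- function(sample, time, event, age_group = NA,
                           gender = NA, stage_group = NA,
                           lymphatic_invasion = NA) {
  if (anyDuplicated(sample))
    stopf("duplicate sample ids in clinical table")
  if (any(!is.finite(time)) || any(time < 0))
    stopf("clinical time must be finite and >= 0 (offending sample: %s)",
          sample[which(!is.finite(time) | time < 0)[1]])
  if (!all(event %in% c(0, 1)))
    stopf("clinical event must be 0 or 1 (offending sample: %s)",
          sample[which(!event %in% c(0, 1))[1]])
  df <- data.frame(sample = as.character(sample), time = time,
                   event = as.integer(event),
                   age_group = rep_len(as.character(age_group), length(sample)),
                   gender = rep_len(as.character(gender), length(sample)),
                   stage_group = rep_len(as.character(stage_group), length(sample)),
                   lymphatic_invasion = rep_len(as.character(lymphatic_invasion),
                                                length(sample)),
                   stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

encode_age <- function(age) {
  a <- suppressWarnings(as.numeric(age))
  out <- ifelse(is.na(a), NA_character_, ifelse(a >= 50, ">=50", "<50"))
  # pre-encoded values pass through
  ch <- str_trim(tolower(as.character(age)))
  out[ch %in% c(">=50", "≥50")] <- ">=50"
  out[ch == "<50"] <- "<50"
  out
}

encode_stage <- function(stage) {
  s <- toupper(gsub("^\\s*STAGE\\s*", "", str_trim(as.character(stage)),
                    ignore.case = TRUE))
  core <- sub("^(IV|III|II|I).*", "\\1", s)
  ifelse(core %in% c("I", "II"), "I-II",
         ifelse(core %in% c("III", "IV"), "III-IV", NA_character_))
}

encode_level <- function(x, levels) {
  v <- str_trim(tolower(as.character(x)))
  ifelse(v %in% levels, v, NA_character_)
}

#' Write subnetworks to GMT with a JSON sidecar
#'
#' One GMT line per subnetwork: the id, a description listing the seed
#' members, then all member genes. The up/down partitions (which GMT cannot
#' hold) go to `<path>.json`.
#'
#' @param subnets A non-empty list of subnetworks (see [filter_subnetworks()]).
#' @param path Output GMT path; the sidecar is written to `paste0(path, ".json")`.
#' @return Invisibly, the GMT path.
#' @export
write_subnetworks <- function(subnets, path) {
  if (!length(subnets)) stopf("nothing to write: empty subnetwork list")
  lines <- vapply(subnets, function(s) {
    paste(c(paste0("subnetwork_", s$id),
            paste0("seeds:", paste(sort(s$seed_members), collapse = ",")),
            sort(s$members)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  sidecar <- lapply(subnets, function(s) {
    list(id = s$id, members = sort(s$members),
         seed_members = sort(s$seed_members),
         up_set = sort(s$up_set), down_set = sort(s$down_set))
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read subnetworks written by [write_subnetworks()]
#'
#' @param path GMT path; if `paste0(path, ".json")` exists the up/down
#'   partitions are restored from it.
#' @return List of subnetwork objects.
#' @export
read_subnetworks <- function(path) {
  if (!file.exists(path)) stopf("subnetwork file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines))]
  subnets <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3L)
      stopf("line %d of '%s': GMT line needs id, description and >=1 gene", i, path)
    seeds <- sub("^seeds:", "", tok[2])
    seeds <- if (nzchar(seeds)) strsplit(seeds, ",", fixed = TRUE)[[1]] else character(0)
    list(id = as.integer(sub("^subnetwork_", "", tok[1])),
         members = tok[-(1:2)], seed_members = seeds,
         up_set = character(0), down_set = character(0))
  })
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    parts <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (i in seq_along(subnets)) {
      j <- which(parts$id == subnets[[i]]$id)
      if (length(j) == 1L) {
        subnets[[i]]$up_set <- as.character(unlist(parts$up_set[j]))
        subnets[[i]]$down_set <- as.character(unlist(parts$down_set[j]))
      }
    }
  }
  subnets
}

#' Read annotation sets from a GMT file
#'
#' @param path GMT path (term, description, member genes...).
#' @return Named list of character vectors (term -> genes), with attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(str_trim(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3L)
      stopf("line %d of '%s': GMT line needs term, description and >=1 gene",
            i, path)
    sets[[tok[1]]] <- unique(str_trim(tok[-(1:2)]))
    desc[tok[1]] <- tok[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write an expression matrix to TSV
#'
#' @param expr An [expression_matrix()] object.
#' @param path Output TSV path; class labels (if any) go to
#'   `paste0(path, ".labels.tsv")`.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(expr$class_labels)) {
    utils::write.table(
      data.frame(sample = names(expr$class_labels),
                 label = unname(expr$class_labels)),
      paste0(path, ".labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
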