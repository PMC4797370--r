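#' Read a haplotype (allele-class) table
#'
#' A haplotype table names the defining polymorphic sites of a gene and maps
#' named allele classes (e.g. Gn1a Types 1-3, GS5 WG/MG/NG) to allele-vector
#' patterns over those sites. Patterns may use "*" as a wildcard; classes
#' flagged `provisional` rest on sequence evidence not fully printed in the
#' primary sources and should be treated as editable transcriptions.
#'
#' @param path YAML file with fields `gene`, `sites` (each with `id`,
#'   `alleles`, optional `description`) and `classes` (each with `name`,
#'   `pattern`, optional `description`, `provisional`).
#' @return List of class `asm_haplotype_table`.
#' @export
read_haplotype_table <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$gene), length(y$sites) > 0, length(y$classes) > 0)
  site_ids <- vapply(y$sites, `[[`, character(1), "id")
  for (cl in y$classes) {
    if (length(cl$pattern) != length(site_ids)) {
      stop(sprintf("class %s pattern length != number of sites", cl$name),
           call. = FALSE)
    }
  }
  h <- structure(list(gene = y$gene, sites = y$sites, classes = y$classes,
                      site_ids = site_ids),
                 class = "asm_haplotype_table")
  .check_patterns_exclusive(h)
  h
}

.check_patterns_exclusive <- function(h) {
  pats <- lapply(h$classes, function(cl) as.character(cl$pattern))
  n <- length(pats)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- pats[[i]]; b <- pats[[j]]
    separable <- any(a != "*" & b != "*" & a != b)
    if (!separable) {
      stop(sprintf("classes %s and %s are not mutually exclusive",
                   h$classes[[i]]$name, h$classes[[j]]$name), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.asm_haplotype_table <- function(x, ...) {
  cat(sprintf("<asm_haplotype_table> %s: %d sites, %d classes\n", x$gene,
              length(x$sites), length(x$classes)))
  for (cl in x$classes) {
    cat(sprintf("  %s: %s%s\n", cl$name, paste(cl$pattern, collapse = "/"),
                if (isTRUE(cl$provisional)) " [provisional]" else ""))
  }
  invisible(x)
}

#' Read a variety-by-site genotype panel
#'
#' @param path CSV with a `variety` column and one column per defining site;
#'   missing data coded "?".
#' @return data.frame.
#' @export
read_panel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"variety" %in% names(p)) stop("panel needs a 'variety' column",
                                     call. = FALSE)
  p
}

.pattern_matches <- function(pattern, vec) {
  all(pattern == "*" | (vec != "?" & vec == pattern))
}

#' Classify varieties into named allele classes
#'
#' Each variety's allele vector over the table's defining sites is matched
#' against the class patterns; novel patterns are reported as "unclassified",
#' never force-assigned to the nearest class.
#'
#' @param panel data.frame from [read_panel()] (columns: `variety` plus the
#'   table's site ids) or a named list of allele vectors.
#' @param h An [read_haplotype_table()] table.
#' @return data.frame with columns `variety`, `class`.
#' @export
classify_haplotypes <- function(panel, h) {
  if (is.list(panel) && !is.data.frame(panel)) {
    panel <- do.call(rbind, lapply(names(panel), function(nm) {
      v <- panel[[nm]]
      df <- as.data.frame(as.list(v), stringsAsFactors = FALSE)
      names(df) <- h$site_ids
      cbind(data.frame(variety = nm, stringsAsFactors = FALSE), df)
    }))
  }
  missing_sites <- setdiff(h$site_ids, names(panel))
  if (length(missing_sites)) {
    stop("panel lacks site column(s): ", paste(missing_sites, collapse = ", "),
         call. = FALSE)
  }
  cls <- vapply(seq_len(nrow(panel)), function(i) {
    vec <- as.character(unlist(panel[i, h$site_ids]))
    hits <- vapply(h$classes, function(cl)
      .pattern_matches(as.character(cl$pattern), vec), logical(1))
    if (sum(hits) == 1) h$classes[[which(hits)]]$name else "unclassified"
  }, character(1))
  data.frame(variety = panel$variety, class = cls, stringsAsFactors = FALSE)
}

#' Count varieties per allele class
#'
#' @param classification data.frame from [classify_haplotypes()].
#' @param h The haplotype table (fixes the class order of the output).
#' @return Named integer vector in table order, with a trailing
#'   `unclassified` count.
#' @export
summarize_haplotypes <- function(classification, h) {
  if (!nrow(classification)) {
    cls <- vapply(h$classes, `[[`, character(1), "name")
    return(stats::setNames(integer(length(cls) + 1), c(cls, "unclassified")))
  }
  cls <- vapply(h$classes, `[[`, character(1), "name")
  counts <- vapply(c(cls, "unclassified"), function(k)
    sum(classification$class == k), integer(1))
  counts
}

#' Generate a random genotype panel from class patterns
#'
#' Draws varieties from the table's classes (wildcard sites filled with a
#' random allele of that site), recording the generating class as ground
#' truth. Used for classification round-trip checks.
#'
#' @param h Haplotype table.
#' @param n Number of varieties.
#' @return List with `panel` (data.frame) and `truth` (character vector of
#'   generating classes).
#' @export
random_panel <- function(h, n) {
  k <- length(h$classes)
  picks <- sample(k, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    cl <- h$classes[[picks[i]]]
    vec <- as.character(cl$pattern)
    for (j in seq_along(vec)) {
      if (vec[j] == "*") {
        vec[j] <- sample(as.character(h$sites[[j]]$alleles), 1)
      }
    }
    df <- as.data.frame(as.list(vec), stringsAsFactors = FALSE)
    names(df) <- h$site_ids
    cbind(data.frame(variety = sprintf("sim%03d", i),
                     stringsAsFactors = FALSE), df)
  })
  list(panel = do.call(rbind, rows),
       truth = vapply(picks, function(i) h$classes[[i]]$name, character(1)))
}

#' Packaged haplotype table or panel path
#'
#' @param gene One of "gn1a", "gs5", "nal1", "ghd7".
#' @param what "table" (YAML) or "panel" (CSV of the 12 recipient varieties).
#' @return File path inside the installed package.
#' @export
haplotype_file <- function(gene = c("gn1a", "gs5", "nal1", "ghd7"),
                           what = c("table", "panel")) {
  gene <- match.arg(gene); what <- match.arg(what)
  f <- if (what == "table") {
    system.file("extdata", "haplotypes", paste0(gene, ".yaml"),
                package = "asmarker")
  } else {
    system.file("extdata", "panels", paste0(gene, "_recipients.csv"),
                package = "asmarker")
  }
  if (!nzchar(f)) stop("packaged file not found for ", gene, call. = FALSE)
  f
}
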