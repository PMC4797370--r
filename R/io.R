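#' Read a primer table
#'
#' Tab-separated table in the packaged dialect: columns `marker`,
#' `polymorphism`, `primer`, `sequence`, where a lowercase letter in
#' `sequence` marks the engineered allele-specificity mismatch (preserved on
#' read as the primer's `mismatch` annotation). Strand is inferred from the
#' primer-name suffix (ending in F = forward, R = reverse).
#'
#' @param path TSV file.
#' @return List with `table` (the parsed data.frame) and `primers` (named
#'   list of [primer()] objects).
#' @export
read_primer_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty primer table: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("marker", "polymorphism", "primer", "sequence")
  if (!all(need %in% header)) {
    stop("primer table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      stop(sprintf("%s line %d: expected %d fields, got %d", path, i,
                   length(header), length(f)), call. = FALSE)
    }
    stats::setNames(as.list(f), header)
  })
  tab <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  primers <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$primer[i]
    strand <- if (grepl("F[0-9]*$|F$", nm)) "forward" else
      if (grepl("R[0-9]*$|R$", nm)) "reverse" else "forward"
    tryCatch(
      primer(nm, tab$sequence[i], strand = strand, role = "common_outer"),
      error = function(e) stop(sprintf("%s line %d (%s): %s", path, i + 1L,
                                       nm, conditionMessage(e)),
                               call. = FALSE))
  })
  names(primers) <- tab$primer
  list(table = tab, primers = primers)
}

#' Write a primer table
#'
#' @param primers Named list of [primer()] objects.
#' @param path Output TSV.
#' @param marker,polymorphism Recycled annotation columns.
#' @export
write_primer_table <- function(primers, path, marker = "marker",
                               polymorphism = "") {
  df <- data.frame(
    marker = marker, polymorphism = polymorphism,
    primer = vapply(primers, `[[`, character(1), "name"),
    sequence = vapply(primers, `[[`, character(1), "display_sequence"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a minimal variant table (VCF-like)
#'
#' Accepts either the package's TSV (columns `locus`, `pos_1based`, `type`,
#' `ref`, `alt`, ...) or a minimal VCF (CHROM/POS/REF/ALT; 1-based anchored
#' indels are converted to the package's pure-indel, 0-based convention).
#'
#' @param path File path; VCF detected by the `.vcf` extension or a
#'   `##fileformat=VCF` first line.
#' @return List of [variant()] objects with a `locus` attribute per entry.
#' @export
read_variant_table <- function(path) {
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf$", path) || grepl("^##fileformat=VCF", first)
  if (is_vcf) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "##")]
    lines <- lines[!startsWith(lines, "#")]
    out <- lapply(lines[nzchar(lines)], function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 4) stop("malformed VCF record: ", ln, call. = FALSE)
      pos <- as.integer(f[2]); ref <- toupper(f[3]); alt <- toupper(f[4])
      if (nchar(ref) == nchar(alt)) {
        v <- variant(pos - 1L, ref, alt)
      } else if (substr(ref, 1, 1) == substr(alt, 1, 1)) {
        # strip the shared anchor base
        v <- variant(pos, substr(ref, 2, nchar(ref)),
                     substr(alt, 2, nchar(alt)))
      } else {
        v <- variant(pos - 1L, ref, alt)
      }
      attr(v, "locus") <- f[1]
      v
    })
    return(out)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ref <- if (df$ref[i] == "-") "" else df$ref[i]
    alt <- if (df$alt[i] == "-") "" else df$alt[i]
    v <- variant(df$pos_1based[i] - 1L, ref, alt,
                 donor_specific = if ("donor_specific" %in% names(df))
                   df$donor_specific[i] else NA)
    attr(v, "locus") <- df$locus[i]
    v
  })
}

#' Write a variant table
#'
#' @param variants List of [variant()] objects.
#' @param path Output TSV (1-based positions).
#' @param locus_id Locus column value.
#' @export
write_variant_table <- function(variants, path, locus_id = "locus") {
  utils::write.table(variant_table(variants, locus_id), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.design_to_list <- function(d) {
  list(
    name = d$name, architecture = d$architecture,
    positive_allele = d$positive_allele,
    recommended_gel = d$recommended_gel,
    primers = lapply(unname(d$primers), function(p) list(
      name = p$name, sequence = p$display_sequence, strand = p$strand,
      role = p$role, tm = round(p$tm, 1),
      artificial_mismatch = if (is.null(p$mismatch)) NULL else
        list(offset_from_3prime = p$mismatch$offset_from_3prime,
             base = p$mismatch$base))),
    reactions = d$reactions,
    expected_products = lapply(
      split(d$expected_products$length, d$expected_products$allele), as.list)
  )
}

#' Write a marker design (or fixture) to JSON
#'
#' @param d An `asm_marker_design` or `asm_marker_fixture`.
#' @param path Output file.
#' @export
write_marker_json <- function(d, path) {
  x <- .design_to_list(d)
  if (inherits(d, "asm_marker_fixture")) {
    x$name <- d$marker
    x$polymorphism <- d$polymorphism
    x$size_exact <- d$size_exact
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write predicted amplicons to TSV
#'
#' @param amp data.frame from [amplify()].
#' @param path Output file.
#' @param reaction Reaction label column.
#' @export
write_amplicon_table <- function(amp, path, reaction = "main") {
  df <- cbind(data.frame(reaction = reaction, stringsAsFactors = FALSE),
              amp[, c("template", "forward", "reverse", "length",
                      "efficiency")])
  names(df)[names(df) == "length"] <- "length_bp"
  df$efficiency <- round(df$efficiency, 4)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' All tunable model parameters with their defaults, serialized alongside
#' outputs so a run can be reproduced exactly.
#'
#' @param seed RNG seed recorded for the run.
#' @return List of class `asm_run_config`.
#' @export
run_config <- function(seed = 1L) {
  structure(list(
    mismatch_model = unclass(mismatch_model()),
    gel_models = gel_models(),
    design_constraints = unclass(design_constraints()),
    efficiency_lambda = 0.002,
    imbalance_ratio = 3,
    display_floor = 0.05,
    seed = as.integer(seed)
  ), class = "asm_run_config")
}

write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
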