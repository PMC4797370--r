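#' Electrophoresis system models
#'
#' Resolution limits and usable size ranges for the four detection systems the
#' markers are scored on. The resolvable-gap thresholds are calibrated
#' choices, set so that the recommended system for each packaged marker
#' matches field practice (a ~4-bp difference needs PAGE or capillary, 12-20
#' bp need 4\% agarose at small product sizes, gaps of ~25 bp and more run on
#' 2.5\% agarose); they can be overridden by passing a modified model.
#'
#' @return Named list of gel models in increasing-cost order, each with
#'   `id`, `min_resolvable_gap` (bp; two products closer than this co-migrate)
#'   and `max_product` (bp).
#' @export
gel_models <- function() {
  list(
    agarose_2.5 = list(id = "agarose_2.5", min_resolvable_gap = 25L,
                       max_product = 3000L),
    agarose_4   = list(id = "agarose_4", min_resolvable_gap = 8L,
                       max_product = 300L),
    page_8      = list(id = "page_8", min_resolvable_gap = 3L,
                       max_product = 1000L),
    capillary   = list(id = "capillary", min_resolvable_gap = 2L,
                       max_product = 6000L)
  )
}

gel_model <- function(id) {
  g <- gel_models()[[id]]
  if (is.null(g)) stop("unknown gel model: ", id, call. = FALSE)
  g
}

# Cluster band lengths that co-migrate on a gel: sorted lengths are split
# where neighbours differ by at least the resolvable gap.
.comigrate_clusters <- function(lengths, g) {
  u <- sort(unique(lengths))
  if (!length(u)) return(integer(0))
  cl <- cumsum(c(1L, diff(u) >= g$min_resolvable_gap))
  stats::setNames(cl, u)
}

#' Resolve amplicons into visible gel bands
#'
#' Products whose lengths differ by less than the gel's resolvable gap merge
#' into a single band; bands whose summed relative efficiency falls below the
#' display floor are too faint to score and are dropped.
#'
#' @param amplicons data.frame from [amplify()] (columns `length`,
#'   `efficiency`), or a bare numeric vector of lengths (unit efficiency).
#' @param g A gel model from [gel_models()] or its id.
#' @param display_floor Minimum summed efficiency for a band to be visible.
#' @return data.frame with one row per visible band: `length`
#'   (intensity-weighted mean of merged lengths), `members` (the merged
#'   product lengths), `intensity`, `resolved` (FALSE for products exceeding
#'   the gel's size range, reported with a warning).
#' @export
resolve_bands <- function(amplicons, g, display_floor = 0.05) {
  if (is.character(g)) g <- gel_model(g)
  if (is.numeric(amplicons)) {
    amplicons <- data.frame(length = amplicons,
                            efficiency = rep(1, length(amplicons)))
  }
  if (!nrow(amplicons)) {
    return(data.frame(length = numeric(), members = character(),
                      intensity = numeric(), resolved = logical(),
                      stringsAsFactors = FALSE))
  }
  over <- amplicons$length > g$max_product
  if (any(over)) {
    warning(sprintf("%d product(s) exceed %s size range (%d bp); flagged unresolved",
                    sum(over), g$id, g$max_product))
  }
  cl <- .comigrate_clusters(amplicons$length, g)
  key <- cl[as.character(amplicons$length)]
  bands <- lapply(split(seq_len(nrow(amplicons)), key), function(i) {
    eff <- sum(amplicons$efficiency[i])
    data.frame(
      length = stats::weighted.mean(amplicons$length[i],
                                    amplicons$efficiency[i]),
      members = paste(sort(unique(amplicons$length[i])), collapse = "/"),
      intensity = eff, resolved = !any(amplicons$length[i] > g$max_product),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, bands)
  out <- out[out$intensity >= display_floor, , drop = FALSE]
  out <- out[order(out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-allele band signatures of a design on a gel: for each reaction, the
# expected lengths of all alleles are clustered jointly and each allele is
# summarized as the set of (reaction, cluster) bands it produces.
.design_signatures <- function(d, g) {
  ep <- d$expected_products
  sig <- lapply(unique(ep$allele), function(a) character(0))
  names(sig) <- unique(ep$allele)
  for (r in unique(ep$reaction)) {
    er <- ep[ep$reaction == r, , drop = FALSE]
    cl <- .comigrate_clusters(er$length, g)
    for (a in names(sig)) {
      la <- er$length[er$allele == a]
      sig[[a]] <- c(sig[[a]], paste0(r, ":", cl[as.character(la)]))
    }
  }
  lapply(sig, function(s) sort(unique(s)))
}

.design_distinguishes <- function(d, g) {
  if (any(d$expected_products$length > g$max_product)) return(FALSE)
  sig <- .design_signatures(d, g)
  if (length(sig) < 2) return(TRUE)
  pairs <- utils::combn(names(sig), 2, simplify = FALSE)
  all(vapply(pairs, function(p) !identical(sig[[p[1]]], sig[[p[2]]]),
             logical(1)))
}

#' Recommend the cheapest electrophoresis system for a marker design
#'
#' Walks the systems in increasing-cost order (2.5\% agarose, 4\% agarose,
#' 8\% PAGE, capillary) and returns the first on which every pair of allele
#' labels yields distinguishable band patterns within the system's size range.
#' Capillary electrophoresis is the fallback.
#'
#' @param d A marker design (see [design_indel_marker()] and friends) with
#'   populated `expected_products`.
#' @return A gel model (list with `id`, `min_resolvable_gap`, `max_product`).
#' @export
recommend_gel <- function(d) {
  stopifnot(!is.null(d$expected_products), nrow(d$expected_products) > 0)
  for (g in gel_models()) {
    if (.design_distinguishes(d, g)) return(g)
  }
  gel_model("capillary")
}

#' Call a genotype from observed bands
#'
#' Scores a sample as PP (homozygous positive allele), NN (homozygous
#' non-target allele), PN (heterozygote) or invalid, by matching observed band
#' lengths per reaction against the design's expected products at the gel's
#' resolution.
#'
#' @param observed Named list mapping reaction name to a numeric vector of
#'   observed band lengths; a bare numeric vector is accepted for
#'   single-reaction designs.
#' @param d The marker design.
#' @param g Gel model (or id); defaults to the design's recommended gel.
#' @param sample Sample identifier carried into the result.
#' @return List of class `asm_genotype_call`: `sample`, `marker`, `call`
#'   (PP/NN/PN/invalid), `bands` (per-band assignment), `note`.
#' @export
call_genotype <- function(observed, d, g = NULL, sample = "sample") {
  g <- if (is.null(g)) gel_model(d$recommended_gel) else
    if (is.character(g)) gel_model(g) else g
  reactions <- unique(d$expected_products$reaction)
  if (!is.list(observed)) {
    if (length(reactions) != 1) {
      stop("design has multiple reactions; pass a named list of bands",
           call. = FALSE)
    }
    observed <- stats::setNames(list(observed), reactions)
  }
  if (!all(names(observed) %in% reactions)) {
    stop("observed bands name unknown reaction(s): ",
         paste(setdiff(names(observed), reactions), collapse = ", "),
         call. = FALSE)
  }
  pos <- d$positive_allele
  ep <- d$expected_products
  alleles <- unique(ep$allele)
  tol <- max(1L, g$min_resolvable_gap - 1L)
  evid_pos <- FALSE; evid_neg <- FALSE
  common_seen <- FALSE; common_expected <- FALSE
  rows <- list(); unmatched <- numeric(0)
  for (r in reactions) {
    er <- ep[ep$reaction == r, , drop = FALSE]
    cl <- .comigrate_clusters(er$length, g)
    obs <- observed[[r]]
    if (is.null(obs)) obs <- numeric(0)
    cl_alleles <- lapply(split(er$allele, cl[as.character(er$length)]), unique)
    cl_len <- vapply(split(er$length, cl[as.character(er$length)]), mean,
                     numeric(1))
    common_expected <- common_expected ||
      any(vapply(cl_alleles, function(a) all(alleles %in% a), logical(1)))
    for (b in obs) {
      dist <- abs(cl_len - b)
      if (!length(dist) || min(dist) > tol) {
        unmatched <- c(unmatched, b)
        next
      }
      k <- names(cl_len)[which.min(dist)]
      owners <- cl_alleles[[k]]
      kind <- if (all(alleles %in% owners)) "common"
      else if (pos %in% owners) "positive" else "non_target"
      if (kind == "positive") evid_pos <- TRUE
      if (kind == "non_target") evid_neg <- TRUE
      if (kind == "common") common_seen <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = r, band = b, assigned = kind,
        expected = round(cl_len[[k]]), stringsAsFactors = FALSE)
    }
  }
  note <- NULL
  call <- if (length(unmatched)) {
    note <- paste("unexpected band(s):", paste(unmatched, collapse = ", "))
    "invalid"
  } else if (!evid_pos && !evid_neg) {
    note <- "no diagnostic bands"
    "invalid"
  } else if (common_expected && !common_seen) {
    note <- "expected common band absent (failed reaction?)"
    "invalid"
  } else if (evid_pos && evid_neg) "PN" else if (evid_pos) "PP" else "NN"
  structure(list(sample = sample, marker = d$name %||% d$marker, call = call,
                 bands = if (length(rows)) do.call(rbind, rows) else NULL,
                 note = note),
            class = "asm_genotype_call")
}

#' @export
print.asm_genotype_call <- function(x, ...) {
  cat(sprintf("<genotype> %s / %s: %s%s\n", x$sample, x$marker, x$call,
              if (!is.null(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Simulate the observed band pattern of a known genotype
#'
#' Runs in-silico PCR for every reaction of a design (or fixture) on the
#' templates corresponding to a PP, NN or PN genotype and resolves the
#' products on a gel, yielding the band lengths a scorer would record.
#'
#' @param d A marker design or fixture with `templates` (positive allele
#'   first is not assumed; alleles are matched via `positive_allele`).
#' @param genotype "PP", "NN" or "PN".
#' @param g Gel model or id; defaults to the design's recommendation.
#' @param display_floor Passed to [resolve_bands()].
#' @return Named list mapping reaction name to a numeric vector of band
#'   lengths, suitable for [call_genotype()].
#' @export
simulate_bands <- function(d, genotype = c("PP", "NN", "PN"), g = NULL,
                           display_floor = 0.05) {
  genotype <- match.arg(genotype)
  g <- if (is.null(g)) gel_model(d$recommended_gel) else
    if (is.character(g)) gel_model(g) else g
  labels <- vapply(d$templates, `[[`, character(1), "allele_label")
  pos_t <- d$templates[[which(labels == d$positive_allele)]]
  neg_t <- d$templates[[which(labels != d$positive_allele)[1]]]
  out <- list()
  for (r in names(d$reactions)) {
    prs <- d$primers[d$reactions[[r]]]
    amp <- switch(genotype,
      PP = amplify(prs, pos_t),
      NN = amplify(prs, neg_t),
      PN = simulate_heterozygote(amplify(prs, pos_t),
                                 amplify(prs, neg_t))$amplicons)
    bands <- resolve_bands(amp, g, display_floor = display_floor)
    out[[r]] <- bands$length
  }
  out
}
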