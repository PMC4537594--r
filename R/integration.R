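# Multi-platform candidate integration: platform membership, Venn
# partition, protein-class summaries from a static annotation snapshot.

#' Integrate per-platform candidate lists
#'
#' @param per_platform Named list mapping each platform (`tissue`,
#'   `cell_line`, `conditioned_medium`) to a character vector of accessions
#'   or a tibble with an `accession` column.
#' @return Membership tibble: `accession` plus one logical column per
#'   platform, sorted by accession.
#' @export
integrate_platforms <- function(per_platform) {
  platforms <- c("tissue", "cell_line", "conditioned_medium")
  sets <- lapply(platforms, function(p) {
    x <- per_platform[[p]]
    if (is.null(x)) {
      return(character(0))
    }
    if (is.data.frame(x)) x <- x$accession
    unique(as.character(x))
  })
  names(sets) <- platforms
  accs <- sort(unique(unlist(sets)))
  out <- tibble(accession = accs)
  for (p in platforms) out[[p]] <- accs %in% sets[[p]]
  out
}

#' Venn partition of a three-platform membership
#'
#' Exact counts of the seven membership regions, plus the derived fractions
#' (round-half-up integer percent) reported alongside: markers found on
#' exactly one platform and markers found on all three.
#'
#' @param membership Membership tibble (see [integrate_platforms()] or
#'   [generate_discovery_fixture()]).
#' @return List of class `venn_partition`: `regions` (named integer vector),
#'   `total`, `platform_totals`, `pct_exactly_one`, `pct_all_three`.
#' @export
venn_partition <- function(membership) {
  if (nrow(membership) == 0) {
    return(structure(
      list(
        regions = setNames(integer(7), names(FIXTURE_REGIONS)),
        total = 0L,
        platform_totals = c(tissue = 0L, cell_line = 0L, conditioned_medium = 0L),
        pct_exactly_one = NA_integer_, pct_all_three = NA_integer_
      ),
      class = "venn_partition"
    ))
  }
  t <- membership$tissue
  c_ <- membership$cell_line
  m <- membership$conditioned_medium
  if (any(!(t | c_ | m))) {
    stop_invalid("every marker must belong to at least one platform")
  }
  regions <- c(
    tissue_only = sum(t & !c_ & !m),
    cell_line_only = sum(!t & c_ & !m),
    conditioned_medium_only = sum(!t & !c_ & m),
    tissue_cell_line = sum(t & c_ & !m),
    tissue_conditioned_medium = sum(t & !c_ & m),
    cell_line_conditioned_medium = sum(!t & c_ & m),
    all_three = sum(t & c_ & m)
  )
  total <- nrow(membership)
  exactly_one <- sum(regions[1:3])
  structure(
    list(
      regions = regions,
      total = total,
      platform_totals = c(
        tissue = sum(t), cell_line = sum(c_), conditioned_medium = sum(m)
      ),
      pct_exactly_one = percent_round(exactly_one / total),
      pct_all_three = percent_round(regions[["all_three"]] / total)
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>", x$total, "markers\n")
  print(x$regions)
  cat(sprintf(
    "exactly one platform: %d%%; all three: %d%%\n",
    x$pct_exactly_one, x$pct_all_three
  ))
  invisible(x)
}

#' Fraction of overlap markers resolved in the same cell lines
#'
#' Among markers found in both the cell-line membrane and conditioned-medium
#' programs, the fraction whose discovery came from the same cell lines
#' (fixture metadata carried on the membership table).
#'
#' @param membership Membership tibble with a `resolved_same_cell_line`
#'   column.
#' @return List: `n_overlap`, `n_same_line`, `pct` (round-half-up percent).
#' @export
same_line_fraction <- function(membership) {
  overlap <- membership$cell_line & membership$conditioned_medium
  n_same <- sum(membership$resolved_same_cell_line[overlap], na.rm = TRUE)
  list(
    n_overlap = sum(overlap),
    n_same_line = n_same,
    pct = percent_round(n_same / sum(overlap))
  )
}

#' Protein-class frequency summary
#'
#' Class counts and round-half-up percentages over a chosen marker subset,
#' with unclassified markers reported as a coverage fraction.
#'
#' @param membership Membership tibble.
#' @param annotations Tibble with `accession` and `protein_class` (NA =
#'   unclassified).
#' @param subset One of `"all"`, `"tissue"`, `"cell_line"`,
#'   `"conditioned_medium"`.
#' @return List: `classes` (tibble `protein_class`, `n`, `pct` of subset),
#'   `n_markers`, `n_classified`, `coverage_pct`.
#' @export
summarize_protein_classes <- function(membership, annotations,
                                      subset = c(
                                        "all", "tissue", "cell_line",
                                        "conditioned_medium"
                                      )) {
  subset <- match.arg(subset)
  accs <- if (subset == "all") {
    membership$accession
  } else {
    membership$accession[membership[[subset]]]
  }
  ann <- annotations[match(accs, annotations$accession), ]
  classified <- !is.na(ann$protein_class)
  classes <- ann[classified, ] %>%
    dplyr::count(.data$protein_class, name = "n") %>%
    mutate(pct = percent_round(.data$n / length(accs))) %>%
    arrange(dplyr::desc(.data$n), .data$protein_class)
  list(
    classes = classes,
    n_markers = length(accs),
    n_classified = sum(classified),
    coverage_pct = percent_round(sum(classified) / length(accs))
  )
}
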