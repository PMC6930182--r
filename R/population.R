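VALID_CODES <- list(
  TESTCROSS  = c("nn", "np"),
  INTERCROSS = c("aa", "ab", "bb")
)

#' Longitudinal mapping population
#'
#' Bundles the longitudinal phenotypes and SNP genotypes of a full-sib
#' mapping family: an `n x T` matrix of shoot heights (cm), an `n x T`
#' matrix of shoot diameters (mm) measured at the same `T` occasions, and a
#' marker table.  Each individual's height baseline `h0` is its first
#' non-missing height observation.
#'
#' @param heights,diameters Numeric `n x T` matrices (rows = individuals,
#'   in the same order). `NA` marks a missing occasion; every individual must
#'   have at least 2 non-missing occasions per trait, and heights must be
#'   strictly positive.
#' @param markers A tibble with columns `id`, `chrom`, `pos`, `cross_type`
#'   (`"TESTCROSS"` or `"INTERCROSS"`) and a list-column `codes` of length-`n`
#'   character vectors (testcross codes `nn`/`np`, intercross `aa`/`ab`/`bb`,
#'   `NA` = missing).
#' @param family_id Label for the family.
#' @param ids Individual ids (default `ind1..indn`).
#' @return An object of class `mapping_population`.
#' @export
mapping_population <- function(heights, diameters, markers,
                               family_id = "family1",
                               ids = NULL) {
  heights <- as.matrix(heights)
  diameters <- as.matrix(diameters)
  if (!all(dim(heights) == dim(diameters))) {
    stop("heights and diameters must have identical dimensions", call. = FALSE)
  }
  n <- nrow(heights); T_ <- ncol(heights)
  if (is.null(ids)) ids <- rownames(heights)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicated individual ids", call. = FALSE)
  rownames(heights) <- rownames(diameters) <- ids

  ok_h <- rowSums(!is.na(heights)) >= 2
  ok_d <- rowSums(!is.na(diameters)) >= 2
  if (!all(ok_h & ok_d)) {
    stop("individual(s) with fewer than 2 non-missing occasions: ",
         paste(ids[!(ok_h & ok_d)], collapse = ", "), call. = FALSE)
  }
  if (any(heights <= 0, na.rm = TRUE)) {
    stop("heights must be strictly positive", call. = FALSE)
  }

  markers <- tibble::as_tibble(markers)
  req <- c("id", "chrom", "pos", "cross_type", "codes")
  if (!all(req %in% names(markers))) {
    stop("marker table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(markers$id)) stop("duplicated marker ids", call. = FALSE)
  for (i in seq_len(nrow(markers))) {
    codes <- markers$codes[[i]]
    ct <- markers$cross_type[[i]]
    if (!ct %in% names(VALID_CODES)) {
      stop("marker ", markers$id[[i]], ": unknown cross_type ", ct,
           call. = FALSE)
    }
    if (length(codes) != n) {
      stop("marker ", markers$id[[i]], ": ", length(codes),
           " genotype codes for ", n, " individuals", call. = FALSE)
    }
    bad <- !is.na(codes) & !codes %in% VALID_CODES[[ct]]
    if (any(bad)) {
      stop("marker ", markers$id[[i]], ": unknown genotype code \"",
           codes[bad][1], "\" (individual ", ids[bad][1], ")", call. = FALSE)
    }
  }

  ## per-individual baseline = first non-missing height observation
  h0 <- apply(heights, 1L, function(r) r[which(!is.na(r))[1]])

  structure(
    list(n = n, T = T_, ids = ids, heights = heights, diameters = diameters,
         h0 = h0, markers = markers, family_id = family_id),
    class = "mapping_population"
  )
}

#' @export
print.mapping_population <- function(x, ...) {
  tc <- sum(x$markers$cross_type == "TESTCROSS")
  ic <- sum(x$markers$cross_type == "INTERCROSS")
  cat("<mapping_population> ", x$family_id, ": ", x$n, " individuals x ",
      x$T, " occasions; ", nrow(x$markers), " markers (", tc,
      " testcross, ", ic, " intercross)\n", sep = "")
  invisible(x)
}

## ---- TSV I/O ---------------------------------------------------------------

read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  na = c("", "NA"), progress = FALSE)
}

#' Read a mapping population from phenotype and marker tables
#'
#' Phenotype table: tab-separated, one row per individual and trait, columns
#' `id`, `trait` (`height` or `diameter`), `t1..tT`; missing = empty or `NA`.
#' Marker table: one row per marker, columns `id`, `chrom`, `pos`,
#' `cross_type`, then one `g_<individual>` column per individual.  Lines
#' starting with `#` are metadata comments.
#'
#' @param phenotype_path,marker_path Paths to the two TSV files.
#' @param quiet Suppress the load report.
#' @return A validated [mapping_population()].
#' @export
read_population <- function(phenotype_path, marker_path, quiet = FALSE) {
  ph <- read_tsv_commented(phenotype_path)
  if (!all(c("id", "trait") %in% names(ph))) {
    stop("phenotype file must have columns id, trait, t1..tT", call. = FALSE)
  }
  tcols <- grep("^t[0-9]+$", names(ph), value = TRUE)
  tcols <- tcols[order(as.integer(sub("^t", "", tcols)))]
  if (length(tcols) < 2) stop("phenotype file needs >= 2 occasion columns",
                              call. = FALSE)
  pull_trait <- function(trait) {
    sub <- ph[ph$trait == trait, , drop = FALSE]
    if (anyDuplicated(sub$id)) {
      stop("duplicated individual id in ", trait, " rows: ",
           sub$id[duplicated(sub$id)][1], call. = FALSE)
    }
    m <- as.matrix(sub[, tcols])
    rownames(m) <- sub$id
    m
  }
  hh <- pull_trait("height")
  dd <- pull_trait("diameter")
  if (!setequal(rownames(hh), rownames(dd))) {
    stop("height and diameter rows cover different individual sets",
         call. = FALSE)
  }
  dd <- dd[rownames(hh), , drop = FALSE]

  mk <- read_tsv_commented(marker_path)
  gcols <- grep("^g_", names(mk), value = TRUE)
  g_ids <- sub("^g_", "", gcols)
  if (!setequal(g_ids, rownames(hh))) {
    stop("marker genotype columns do not match the phenotype individual set",
         call. = FALSE)
  }
  ord <- match(rownames(hh), g_ids)
  codes <- purrr::map(seq_len(nrow(mk)), function(i) {
    as.character(unlist(mk[i, gcols], use.names = FALSE))[ord]
  })
  markers <- tibble::tibble(
    id = as.character(mk$id), chrom = as.character(mk$chrom),
    pos = as.numeric(mk$pos), cross_type = toupper(mk$cross_type),
    codes = codes
  )
  pop <- mapping_population(hh, dd, markers, ids = rownames(hh))
  if (!quiet) {
    tc <- sum(markers$cross_type == "TESTCROSS")
    ic <- sum(markers$cross_type == "INTERCROSS")
    message("loaded ", pop$n, " individuals x ", pop$T, " occasions; ",
            nrow(markers), " markers (", tc, " testcross, ", ic,
            " intercross)")
  }
  pop
}

output_header <- function(seed = NULL, extra = character()) {
  ver <- as.character(utils::packageVersion("allonet"))
  c(paste0("# allonet v", ver),
    if (!is.null(seed)) paste0("# seed: ", seed),
    extra)
}

#' Write a mapping population to phenotype and marker TSV files
#'
#' Inverse of [read_population()]; round-trips losslessly.
#'
#' @param pop A [mapping_population()].
#' @param phenotype_path,marker_path Output paths.
#' @param seed Optional seed recorded in the file headers.
#' @return Invisibly, the two paths.
#' @export
write_population <- function(pop, phenotype_path, marker_path, seed = NULL) {
  stopifnot(inherits(pop, "mapping_population"))
  tcols <- paste0("t", seq_len(pop$T))
  mat2tbl <- function(m, trait) {
    out <- tibble::as_tibble(m, .name_repair = ~tcols)
    dplyr::bind_cols(tibble::tibble(id = pop$ids, trait = trait), out)
  }
  ph <- dplyr::bind_rows(mat2tbl(pop$heights, "height"),
                         mat2tbl(pop$diameters, "diameter"))
  writeLines(output_header(seed, paste0("# family: ", pop$family_id)),
             phenotype_path)
  readr::write_tsv(ph, phenotype_path, append = TRUE, col_names = TRUE)

  gm <- do.call(rbind, pop$markers$codes)
  colnames(gm) <- paste0("g_", pop$ids)
  mk <- dplyr::bind_cols(
    pop$markers[, c("id", "chrom", "pos", "cross_type")],
    tibble::as_tibble(gm)
  )
  writeLines(output_header(seed), marker_path)
  readr::write_tsv(mk, marker_path, append = TRUE, col_names = TRUE)
  invisible(c(phenotype_path, marker_path))
}
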