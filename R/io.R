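#' Read a GeneNetwork-style `.geno` genotype file
#'
#' The dialect is tab-separated: metadata lines start with `@` (allele code
#' declarations such as `@mat B`, `@pat D`, `@unk U`, either space- or
#' colon-separated), comment lines with `#`, then a header row
#' `Chr Locus cM Mb <line ids...>` followed by one marker per row.  Calls
#' `B`/`D` are coded 0/1; `U` (unknown) and `H` (heterozygous, impossible in
#' a fully inbred line and therefore treated as a failed call) become
#' missing.
#'
#' Malformed input is rejected with a diagnostic naming the offending file
#' line: duplicate marker names, cM decreasing within a chromosome, unknown
#' call codes, and rows with the wrong number of columns.
#'
#' @param path file path.
#' @return list with elements `map` (a [genetic_map()]) and `geno` (integer
#'   matrix, lines x markers, 0/1/NA).
#' @seealso [write_geno()]
#' @export
read_geno <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*$", raw) & !startsWith(raw, "#")
  meta <- startsWith(raw, "@")

  codes <- c(mat = "B", pat = "D", unk = "U", het = "H")
  for (ml in raw[meta & keep]) {
    m <- regmatches(ml, regexec("^@([a-zA-Z]+)[: ]\\s*(\\S+)", ml))[[1]]
    if (length(m) == 3 && m[2] %in% names(codes)) codes[m[2]] <- m[3]
  }

  body_idx <- which(keep & !meta)
  if (length(body_idx) < 2) stop("no genotype rows in ", path)
  header <- strsplit(raw[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 5 || !identical(header[1:4], c("Chr", "Locus", "cM", "Mb")))
    stop("header must be 'Chr\\tLocus\\tcM\\tMb\\t<line ids>' (line ",
         body_idx[1], ")")
  line_ids <- header[-(1:4)]
  if (anyDuplicated(line_ids)) stop("duplicate line ids in header")

  rows_idx <- body_idx[-1]
  fields <- strsplit(raw[rows_idx], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  bad <- which(nfield != length(header))
  if (length(bad))
    stop("row at line ", rows_idx[bad[1]], " has ", nfield[bad[1]],
         " columns, expected ", length(header))

  mat <- do.call(rbind, fields)
  map_df <- data.frame(marker = mat[, 2], chr = mat[, 1],
                       cM = as.numeric(mat[, 3]), Mb = as.numeric(mat[, 4]),
                       stringsAsFactors = FALSE)
  dup <- which(duplicated(map_df$marker))
  if (length(dup))
    stop("duplicate marker name '", map_df$marker[dup[1]], "' at line ",
         rows_idx[dup[1]])
  for (cc in unique(map_df$chr)) {
    i <- which(map_df$chr == cc)
    drop_ <- which(diff(map_df$cM[i]) < 0)
    if (length(drop_))
      stop("cM decreases on chromosome ", cc, " at line ",
           rows_idx[i[drop_[1] + 1]])
  }

  calls <- mat[, -(1:4), drop = FALSE]
  known <- calls %in% codes
  if (!all(known)) {
    bad_cell <- which(!known)[1]
    bad_row <- (bad_cell - 1) %% nrow(calls) + 1
    stop("unknown genotype code '", calls[bad_cell], "' at line ",
         rows_idx[bad_row])
  }
  G <- matrix(NA_integer_, nrow = length(line_ids), ncol = nrow(map_df),
              dimnames = list(line_ids, map_df$marker))
  G[t(calls) == codes["mat"]] <- 0L
  G[t(calls) == codes["pat"]] <- 1L
  # unk/het remain NA
  list(map = genetic_map(map_df), geno = G)
}

#' Write genotypes in the `.geno` dialect
#'
#' Inverse of [read_geno()]; emits `@mat B`, `@pat D`, `@unk U` metadata.
#'
#' @param map a [genetic_map()].
#' @param G lines x markers matrix coded 0/1/NA, column names matching the
#'   map's markers.
#' @param path output path.
#' @export
write_geno <- function(map, G, path) {
  stopifnot(inherits(map, "genetic_map"))
  if (is.null(dim(G)) || nrow(G) == 0) stop("empty genotype panel")
  if (!identical(colnames(G), map$marker))
    G <- G[, map$marker, drop = FALSE]
  calls <- matrix("U", nrow = ncol(G), ncol = nrow(G))
  tG <- t(G)
  calls[which(tG == 0L)] <- "B"
  calls[which(tG == 1L)] <- "D"
  rows <- paste(map$chr, map$marker,
                format(map$cM, trim = TRUE, digits = 15, scientific = FALSE),
                format(map$Mb, trim = TRUE, digits = 15, scientific = FALSE),
                apply(calls, 1, paste, collapse = "\t"), sep = "\t")
  header <- paste(c("Chr", "Locus", "cM", "Mb", rownames(G)), collapse = "\t")
  writeLines(c("# RI panel genotypes", "@mat B", "@pat D", "@unk U",
               header, rows), path)
  invisible(path)
}

#' Read and validate a family phenotype table
#'
#' The CSV schema has one row per family x day x role x trait:
#' `family_id, line_id, day, role, trait, value`, then the six litter/maternal
#' covariates `maternal_bodyweight, avg_B6_pup_weight, B6_litter_size,
#' avg_BXD_pup_weight, BXD_litter_size, batch`.  Roles are `BXD_offspring`,
#' `B6_offspring`, `mother`; offspring traits are solicitation, sucking and
#' activity, maternal traits suckling and activity; days are 6, 10 and 14.
#' Schema violations raise an error listing the offending rows; rows with
#' missing covariate values are admitted but flagged with a warning (they
#' are dropped later during model fitting).
#'
#' @param path CSV path (comma-separated, `.` decimal, header required).
#' @return a `family_table` data frame.
#' @export
read_pheno <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_family_table(tbl)
}

validate_family_table <- function(tbl) {
  need <- c("family_id", "line_id", "day", "role", "trait", "value", COVARIATES)
  miss <- setdiff(need, names(tbl))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad_role <- which(!(tbl$role %in% ROLES))
  if (length(bad_role))
    stop("unknown role '", tbl$role[bad_role[1]], "' in row(s) ",
         paste(utils::head(bad_role, 5), collapse = ", "))
  bad_day <- which(!(tbl$day %in% DAYS))
  if (length(bad_day))
    stop("day outside {6, 10, 14} in row(s) ",
         paste(utils::head(bad_day, 5), collapse = ", "))
  ok_trait <- ifelse(tbl$role == "mother", tbl$trait %in% MOTHER_TRAITS,
                     tbl$trait %in% OFFSPRING_TRAITS)
  if (any(!ok_trait))
    stop("invalid role/trait combination in row(s) ",
         paste(utils::head(which(!ok_trait), 5), collapse = ", "))
  key <- paste(tbl$family_id, tbl$day, tbl$role, tbl$trait, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (family_id, day, role, trait) in row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  cont <- setdiff(COVARIATES, "batch")
  na_cov <- which(rowSums(is.na(tbl[, cont])) > 0 | is.na(tbl$batch))
  if (length(na_cov))
    warning("missing covariate values in row(s) ",
            paste(utils::head(na_cov, 5), collapse = ", "),
            if (length(na_cov) > 5) " ..." else "")
  class(tbl) <- c("family_table", "data.frame")
  tbl
}

#' @rdname read_pheno
#' @param tbl a family table.
#' @export
write_pheno <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a locus report table as TSV and JSON
#'
#' One row per member effect, direct effects first within each locus, with
#' the columns `locus, phenotype, effect_class, day, peak_Mb, CI_Mb_low,
#' CI_Mb_high, max_LRS, max_LOD, genomewide_p, allele_increasing, R2` plus
#' `p_type` recording whether the p-value is a genome-wide permutation p or
#' a protected point-wise test p.
#'
#' @param reports a list of locus reports from [co_locate()], or the
#'   assembled table from [assemble_locus_table()].
#' @param path base output path; `<path>.tsv` and `<path>.json` are written.
#' @return Invisibly, the two file paths.
#' @export
write_locus_table <- function(reports, path) {
  tbl <- if (is.data.frame(reports)) reports else locus_members_df(reports)
  cols <- c("locus", "phenotype", "effect_class", "day", "peak_Mb",
            "CI_Mb_low", "CI_Mb_high", "max_LRS", "max_LOD", "genomewide_p",
            "allele_increasing", "R2", "p_type")
  for (cc in setdiff(cols, names(tbl))) tbl[[cc]] <- logical(0)[seq_len(nrow(tbl))]
  tbl <- tbl[, cols, drop = FALSE]
  tsv <- paste0(path, ".tsv"); json <- paste0(path, ".json")
  utils::write.table(tbl, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(tbl, json, dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

# flatten a list of locus reports into the member table
locus_members_df <- function(reports) {
  if (!length(reports)) {
    return(data.frame(locus = character(), phenotype = character(),
                      effect_class = character(), day = numeric(),
                      peak_Mb = numeric(), CI_Mb_low = numeric(),
                      CI_Mb_high = numeric(), max_LRS = numeric(),
                      max_LOD = numeric(), genomewide_p = numeric(),
                      allele_increasing = character(), R2 = numeric(),
                      p_type = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(reports, function(rep) {
    m <- rep$members
    m <- m[order(m$effect_class != "direct", m$peak_Mb, m$role, m$trait), ]
    data.frame(locus = rep$name,
               phenotype = phenotype_label(m$role, m$trait),
               effect_class = m$effect_class, day = m$day,
               peak_Mb = m$peak_Mb, CI_Mb_low = m$ci_low,
               CI_Mb_high = m$ci_high, max_LRS = m$max_lrs,
               max_LOD = m$max_lod, genomewide_p = m$p,
               allele_increasing = m$allele_increasing %||% NA_character_,
               R2 = m$R2 %||% NA_real_,
               p_type = m$p_type, stringsAsFactors = FALSE)
  }))
}

phenotype_label <- function(role, trait) {
  lab <- c(BXD_offspring = "BXD sibling", B6_offspring = "B6 sibling",
           mother = "B6 maternal")
  paste(lab[role], trait)
}
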