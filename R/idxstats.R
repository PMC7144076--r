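#' Read a samtools idxstats table
#'
#' Parses the four-column tab-separated summary produced by
#' `samtools idxstats`: reference name, reference length (bp), number of
#' mapped reads, number of unmapped reads.  The `*` placeholder row for
#' unaligned reads is dropped.  Extra trailing columns (tool-version drift)
#' are tolerated and ignored.
#'
#' @param path path to an idxstats text file.
#' @param sample_id sample identifier attached to the table; defaults to
#'   the file name without extension.
#' @return An object of class `idxstats`: a data frame with columns
#'   `name`, `length`, `mapped`, `unmapped` in file order, and attribute
#'   `sample_id`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".idxstats")
#' writeLines(c("chr1\t100\t50\t0", "chrX\t50\t25\t0", "*\t0\t0\t10"), f)
#' read_idxstats(f, "toy")
read_idxstats <- function(path, sample_id = NULL) {
  if (!file.exists(path))
    stop("idxstats file not found: ", path, call. = FALSE)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("no references in idxstats file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 4L))
    stop("parse error at line ", lineno[which(nf < 4L)[1L]],
         ": expected >= 4 tab-separated fields", call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  num <- function(j) suppressWarnings(as.numeric(vapply(fields, `[[`, "", j)))
  len <- num(2L); mapped <- num(3L); unmapped <- num(4L)
  bad <- which(is.na(len) | is.na(mapped) | is.na(unmapped) |
                 len != trunc(len) | mapped != trunc(mapped) |
                 unmapped != trunc(unmapped))
  if (length(bad) > 0L)
    stop("parse error at line ", lineno[bad[1L]],
         ": fields 2-4 must be integers", call. = FALSE)
  drop <- nm == "*"
  nm <- nm[!drop]; len <- len[!drop]
  mapped <- mapped[!drop]; unmapped <- unmapped[!drop]
  if (length(nm) == 0L)
    stop("no references in idxstats file: ", path, call. = FALSE)
  if (any(mapped < 0 | unmapped < 0))
    stop("negative read count in idxstats file: ", path, call. = FALSE)
  if (any(len <= 0))
    stop("non-positive reference length in idxstats file: ", path,
         call. = FALSE)
  idxstats_table(nm, len, mapped, unmapped, sample_id = sample_id)
}

#' Construct an idxstats table in memory
#'
#' @param name,length,mapped,unmapped parallel vectors as in the idxstats
#'   format.  `mapped` may be non-integer for noise-free simulated tables.
#' @param sample_id sample identifier.
#' @return An `idxstats` object.
#' @keywords internal
#' @export
idxstats_table <- function(name, length, mapped, unmapped = 0,
                           sample_id = "sample") {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicated reference names in idxstats table", call. = FALSE)
  if (any(name == "*"))
    stop("the '*' placeholder row must not be stored", call. = FALSE)
  tab <- data.frame(name = name, length = as.numeric(length),
                    mapped = as.numeric(mapped),
                    unmapped = rep_len(as.numeric(unmapped), base::length(name)),
                    stringsAsFactors = FALSE)
  if (any(tab$mapped < 0) || any(tab$unmapped < 0))
    stop("read counts must be non-negative", call. = FALSE)
  attr(tab, "sample_id") <- sample_id
  class(tab) <- c("idxstats", "data.frame")
  tab
}

#' @export
print.idxstats <- function(x, ...) {
  cat(sprintf("idxstats table '%s': %d references, %s mapped reads\n",
              attr(x, "sample_id"), nrow(x),
              format(sum(x$mapped), big.mark = ",")))
  NextMethod()
}

#' @rdname read_idxstats
#' @param table an `idxstats` object.
#' @export
write_idxstats <- function(table, path) {
  stopifnot(inherits(table, "idxstats"))
  writeLines(sprintf("%s\t%s\t%s\t%s", table$name,
                     format(table$length, scientific = FALSE, trim = TRUE),
                     format(table$mapped, scientific = FALSE, trim = TRUE),
                     format(table$unmapped, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

sample_id_of <- function(table) {
  sid <- attr(table, "sample_id")
  if (is.null(sid)) "sample" else sid
}

#' Join alignment counts with a karyotype
#'
#' Attaches roles and authoritative lengths to a sample's per-chromosome
#' mapped counts.  The karyotype owns the lengths; idxstats lengths are
#' only cross-checked (a relative mismatch above 0.1% raises a warning,
#' e.g. a reference/annotation version drift).  Excluded chromosomes are
#' dropped; table rows not in the karyotype (unplaced scaffolds) are
#' ignored with a message.
#'
#' @param table an `idxstats` object.
#' @param kt a [karyotype].
#' @param aliases optional named character vector translating table names
#'   to karyotype names, e.g. `c(X = "chrX")` when the alignment reference
#'   and the karyotype use different naming schemes.
#' @return A data frame of class `rx_counts` with columns `name`, `length`,
#'   `role`, `mapped` (one row per non-excluded karyotype chromosome, in
#'   karyotype order) and attributes `sample_id`, `system`.
#' @export
join_counts <- function(table, kt, aliases = NULL) {
  stopifnot(inherits(table, "idxstats"), inherits(kt, "karyotype"))
  tab_names <- table$name
  if (!is.null(aliases)) {
    hit <- tab_names %in% names(aliases)
    tab_names[hit] <- unname(aliases[tab_names[hit]])
  }
  keep <- kt[kt$role != "excluded", , drop = FALSE]
  idx <- match(keep$name, tab_names)
  core <- keep$role %in% c("autosome", "shared_sex")
  missing_core <- keep$name[core & is.na(idx)]
  if (length(missing_core) > 0L)
    stop("chromosome(s) missing from idxstats table: ",
         paste(missing_core, collapse = ", "), call. = FALSE)
  extra <- setdiff(tab_names, kt$name)
  if (length(extra) > 0L)
    message(length(extra), " reference(s) not in karyotype ignored for '",
            sample_id_of(table), "'")
  # sex-limited chromosome may legitimately be absent (female-derived
  # assemblies carry no Y); treat absence as zero mapped reads
  mapped <- ifelse(is.na(idx), 0, table$mapped[idx])
  tab_len <- table$length[idx]
  mismatch <- !is.na(tab_len) & abs(tab_len - keep$length) / keep$length > 0.001
  if (any(mismatch))
    warning("idxstats length differs from karyotype by > 0.1% for: ",
            paste(keep$name[mismatch], collapse = ", "), call. = FALSE)
  out <- data.frame(name = keep$name, length = keep$length, role = keep$role,
                    mapped = mapped, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id_of(table)
  attr(out, "system") <- karyo_system(kt)
  class(out) <- c("rx_counts", "data.frame")
  out
}
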