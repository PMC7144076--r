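## Valid chromosome roles.  shared_sex is the chromosome present in both
## sexes in different copy number (X under XY, Z under ZW); limited_sex is
## the sex-limited chromosome (Y or W); excluded covers mitochondria and
## unplaced scaffolds, which never enter the Rx statistic.
.ROLES <- c("autosome", "shared_sex", "limited_sex", "excluded")

#' Construct a karyotype
#'
#' A karyotype is the chromosome universe against which a sample's
#' alignment counts are interpreted: the chromosome names as they appear in
#' the alignment reference, their lengths in base pairs, the role of each
#' chromosome, and the sex-determination system.
#'
#' @param name character vector of unique, non-empty chromosome names.
#' @param length positive integer vector of chromosome lengths (bp).
#' @param role character vector of roles, one of `"autosome"`,
#'   `"shared_sex"` (the X in an XY system, the Z in a ZW system),
#'   `"limited_sex"` (Y or W) or `"excluded"`.
#' @param system `"XY"` or `"ZW"`.  Determines how the homogametic /
#'   heterogametic calls are labelled as female / male.
#'
#' @details A valid karyotype has exactly one shared sex chromosome, at most
#'   one sex-limited chromosome, and at least three autosomes: the standard
#'   error of the Rx mean needs at least two autosomal ratio terms and the
#'   coverage regression needs residual degrees of freedom.
#'
#' @return An object of class `karyotype`: a data frame with columns
#'   `name`, `length`, `role` and attribute `system`.
#' @seealso [karyotype_from_fai()], [elephant_karyotype()]
#' @export
#' @examples
#' kt <- karyotype(
#'   name   = c("chr1", "chr2", "chr3", "chrX"),
#'   length = c(100e6, 90e6, 80e6, 60e6),
#'   role   = c("autosome", "autosome", "autosome", "shared_sex"),
#'   system = "XY")
#' kt
karyotype <- function(name, length, role, system = c("XY", "ZW")) {
  system <- match.arg(system)
  name <- as.character(name)
  length <- as.numeric(length)
  role <- as.character(role)
  n <- base::length(name)
  if (base::length(length) != n || base::length(role) != n)
    stop("name, length and role must have equal length", call. = FALSE)
  if (any(!nzchar(name)) || anyNA(name))
    stop("chromosome names must be non-empty", call. = FALSE)
  if (anyDuplicated(name))
    stop("duplicated chromosome names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(length) || any(length <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  bad <- setdiff(unique(role), .ROLES)
  if (base::length(bad) > 0)
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (sum(role == "shared_sex") != 1L)
    stop("karyotype must contain exactly one shared sex chromosome (X or Z)",
         call. = FALSE)
  if (sum(role == "limited_sex") > 1L)
    stop("karyotype may contain at most one sex-limited chromosome (Y or W)",
         call. = FALSE)
  if (sum(role == "autosome") < 3L)
    stop("karyotype must contain at least 3 autosomes", call. = FALSE)
  kt <- data.frame(name = name, length = length, role = role,
                   stringsAsFactors = FALSE)
  attr(kt, "system") <- system
  class(kt) <- c("karyotype", "data.frame")
  kt
}

#' @export
print.karyotype <- function(x, ...) {
  sys <- attr(x, "system")
  tab <- table(factor(x$role, levels = .ROLES))
  cat(sprintf("karyotype (%s system): %d autosomes, %s, %s; %d excluded\n",
              sys, tab[["autosome"]],
              paste0(if (sys == "XY") "X" else "Z", " = ",
                     x$name[x$role == "shared_sex"]),
              if (tab[["limited_sex"]] == 1L)
                paste0(if (sys == "XY") "Y" else "W", " = ",
                       x$name[x$role == "limited_sex"])
              else "no sex-limited chromosome",
              tab[["excluded"]]))
  cat(sprintf("total length of non-excluded chromosomes: %.1f Mb\n",
              sum(x$length[x$role != "excluded"]) / 1e6))
  invisible(x)
}

karyo_system <- function(kt) attr(kt, "system")

#' Build a karyotype from a FASTA index (.fai) file
#'
#' Reads chromosome names and lengths from a `samtools faidx` index and
#' assigns roles, so the Rx computation can be configured for any taxon
#' with a chromosome-level reference assembly.  References not named as
#' autosome, shared or sex-limited chromosome are assigned role
#' `"excluded"` (typical for the mitochondrion and unplaced scaffolds).
#'
#' @param path path to a `.fai` file (>= 2 tab-separated columns:
#'   name, length).
#' @param shared_sex_name name of the X (or Z) chromosome; must be present
#'   in the index.
#' @param autosome_names explicit character vector of autosome names, or
#'   `NULL` to use `autosome_pattern`.
#' @param autosome_pattern a regular expression matched against reference
#'   names to select autosomes (ignored when `autosome_names` is given).
#' @param system `"XY"` or `"ZW"`.
#' @param limited_sex_name optional name of the Y (or W) chromosome.
#' @return A [karyotype] in the order the references appear in the index.
#' @export
#' @examples
#' fai <- system.file("extdata", "synthetic_elephant.fa.fai", package = "rxsex")
#' karyotype_from_fai(fai, shared_sex_name = "chrX",
#'                    autosome_pattern = "^chr([1-9]|1[0-9]|2[0-7])$")
karyotype_from_fai <- function(path, shared_sex_name,
                               autosome_names = NULL,
                               autosome_pattern = NULL,
                               system = c("XY", "ZW"),
                               limited_sex_name = NULL) {
  system <- match.arg(system)
  if (!file.exists(path))
    stop("fai file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("empty fai file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) < 2L))
    stop("fai lines must have at least 2 tab-separated columns", call. = FALSE)
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len))
    stop("non-numeric length in fai file", call. = FALSE)
  if (!shared_sex_name %in% nm)
    stop("shared sex chromosome '", shared_sex_name,
         "' not found in fai file", call. = FALSE)
  if (!is.null(limited_sex_name) && !limited_sex_name %in% nm)
    stop("sex-limited chromosome '", limited_sex_name,
         "' not found in fai file", call. = FALSE)
  if (is.null(autosome_names)) {
    if (is.null(autosome_pattern))
      stop("one of autosome_names or autosome_pattern is required",
           call. = FALSE)
    autosome_names <- grep(autosome_pattern, nm, value = TRUE)
  } else {
    missing_auto <- setdiff(autosome_names, nm)
    if (length(missing_auto) > 0L)
      stop("autosome(s) not found in fai file: ",
           paste(missing_auto, collapse = ", "), call. = FALSE)
  }
  autosome_names <- setdiff(autosome_names,
                            c(shared_sex_name, limited_sex_name))
  if (length(autosome_names) < 3L)
    stop("fewer than 3 autosomes matched (got ", length(autosome_names),
         ")", call. = FALSE)
  role <- rep("excluded", length(nm))
  role[nm %in% autosome_names] <- "autosome"
  role[nm == shared_sex_name] <- "shared_sex"
  if (!is.null(limited_sex_name)) role[nm == limited_sex_name] <- "limited_sex"
  karyotype(nm, len, role, system)
}

#' Read / write a karyotype configuration file
#'
#' The configuration is a plain tab-separated file with columns `name`,
#' `length`, `role` and a header comment line `#system=XY` (or `ZW`), so a
#' taxon configuration can be versioned alongside the data it describes.
#'
#' @param path file path.
#' @return `read_karyotype` returns a [karyotype]; `write_karyotype`
#'   returns `path` invisibly.
#' @export
read_karyotype <- function(path) {
  if (!file.exists(path))
    stop("karyotype file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sysline <- grep("^#\\s*system\\s*=", lines, value = TRUE)
  if (length(sysline) != 1L)
    stop("karyotype file must contain exactly one '#system=' line",
         call. = FALSE)
  system <- toupper(trimws(sub("^#\\s*system\\s*=", "", sysline)))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.table(con, sep = "\t", header = TRUE,
                          colClasses = c("character", "numeric", "character"))
  karyotype(df$name, df$length, df$role, system = system)
}

#' @rdname read_karyotype
#' @param kt a [karyotype].
#' @export
write_karyotype <- function(kt, path) {
  stopifnot(inherits(kt, "karyotype"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#system=", karyo_system(kt)), con)
  writeLines("name\tlength\trole", con)
  writeLines(sprintf("%s\t%s\t%s", kt$name,
                     format(kt$length, scientific = FALSE, trim = TRUE),
                     kt$role), con)
  invisible(path)
}

#' Synthetic African savanna elephant karyotype
#'
#' A stand-in for the chromosome-level savanna elephant assembly: 27
#' autosomes plus one X chromosome (2n = 56; the assembly derives from a
#' female, so no Y is present).  Chromosome lengths are synthetic --
#' a smooth decay from ~228 Mb to ~45 Mb totalling ~3.8 Gb -- chosen to be
#' realistic in scale, not to match any published assembly base for base.
#' Only relative lengths matter to the Rx statistic.
#'
#' @return A [karyotype] with 27 autosomes (`chr1`..`chr27`), `chrX`
#'   (`shared_sex`), and an excluded mitochondrion `chrM`.
#' @export
#' @examples
#' elephant_karyotype()
elephant_karyotype <- function() {
  n_auto <- 27L
  lengths <- round(seq(228e6, 45e6, length.out = n_auto))
  karyotype(
    name   = c(paste0("chr", seq_len(n_auto)), "chrX", "chrM"),
    length = c(lengths, 126e6, 16770),
    role   = c(rep("autosome", n_auto), "shared_sex", "excluded"),
    system = "XY")
}
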