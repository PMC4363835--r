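#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from parallel vectors. Validation enforces:
#' unique ids; parent references that resolve within the pedigree (or are
#' missing — founders); sex-consistent parentage (an individual referenced as
#' a father must not be recorded female, and vice versa; unknown sex of a
#' referenced parent is promoted to the implied sex); acyclic parent links;
#' known sex for every non-founder. One recorded parent is allowed: the
#' missing one is treated as a unique unrelated founder in all kinship
#' computations.
#'
#' @param id Individual identifiers (unique).
#' @param father,mother Parent identifiers; `NA`, `""` or `"0"` mean unknown.
#' @param sex `"male"`, `"female"` or `"unknown"` (also accepts 1/2/0 and
#'   M/F/U codings).
#' @param family Family identifiers (optional; defaults to a single family).
#' @return Object of class `pedigree`: a data frame with columns `family`,
#'   `id`, `father`, `mother`, `sex`, plus integer parent indices and a
#'   generation-depth attribute used internally.
#' @export
pedigree <- function(id, father, mother, sex, family = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (is.null(family)) family <- rep("F1", n)
  norm_parent <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p %in% c("", "0", "NA")] <- NA_character_
    p
  }
  father <- norm_parent(father)
  mother <- norm_parent(mother)
  sex <- normalize_sex(sex)
  stopifnot(length(father) == n, length(mother) == n, length(sex) == n,
            length(family) == n)

  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    stop("duplicate individual id '", dup, "' (row ",
         which(id == dup)[2], ")")
  }
  fidx <- match(father, id)
  midx <- match(mother, id)
  bad <- which(!is.na(father) & is.na(fidx))
  if (length(bad))
    stop("row ", bad[1], ": father '", father[bad[1]], "' not in pedigree")
  bad <- which(!is.na(mother) & is.na(midx))
  if (length(bad))
    stop("row ", bad[1], ": mother '", mother[bad[1]], "' not in pedigree")

  # sex consistency; promote unknown-sex referenced parents
  fa_ref <- unique(fidx[!is.na(fidx)])
  mo_ref <- unique(midx[!is.na(midx)])
  clash <- intersect(fa_ref, mo_ref)
  if (length(clash))
    stop("individual '", id[clash[1]], "' appears as both father and mother")
  bad <- fa_ref[sex[fa_ref] == "female"]
  if (length(bad))
    stop("individual '", id[bad[1]], "' recorded female but referenced as father (row ",
         which(fidx == bad[1])[1], ")")
  bad <- mo_ref[sex[mo_ref] == "male"]
  if (length(bad))
    stop("individual '", id[bad[1]], "' recorded male but referenced as mother (row ",
         which(midx == bad[1])[1], ")")
  sex[fa_ref][sex[fa_ref] == "unknown"] <- "male"
  sex[mo_ref][sex[mo_ref] == "unknown"] <- "female"

  depth <- pedigree_depth(fidx, midx, id)

  nonfounder <- !is.na(fidx) | !is.na(midx)
  bad <- which(nonfounder & sex == "unknown")
  if (length(bad))
    stop("row ", bad[1], " ('", id[bad[1]],
         "'): unknown sex is allowed for founders only")

  ped <- data.frame(family = as.character(family), id = id, father = father,
                    mother = mother, sex = sex, stringsAsFactors = FALSE)
  structure(ped, fidx = fidx, midx = midx, depth = depth,
            class = c("pedigree", "data.frame"))
}

normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  out[s %in% c("0", "u", "unknown", "", "na") | is.na(s)] <- "unknown"
  if (anyNA(out))
    stop("row ", which(is.na(out))[1], ": unrecognized sex code '",
         sex[which(is.na(out))[1]], "'")
  out
}

# generation depth (founders 0); detects cycles in parent links
pedigree_depth <- function(fidx, midx, id) {
  n <- length(fidx)
  depth <- rep(NA_integer_, n)
  depth[is.na(fidx) & is.na(midx)] <- 0L
  for (pass in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) return(depth)
    progressed <- FALSE
    for (i in todo) {
      df <- if (is.na(fidx[i])) 0L else depth[fidx[i]]
      dm <- if (is.na(midx[i])) 0L else depth[midx[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        progressed <- TRUE
      }
    }
    if (!progressed)
      stop("pedigree contains a cycle involving individual '",
           id[which(is.na(depth))[1]], "'")
  }
  depth
}

#' Read a PED-like pedigree file
#'
#' Whitespace- or tab-delimited file with columns family, id, father, mother,
#' sex (the 5-column PED prefix). `0` or blank marks a missing parent; sex is
#' coded 1/2/0 or M/F/U or male/female/unknown. A header line is detected and
#' skipped if the first field is `family` or `fid`.
#'
#' @param path File path.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  first <- tolower(strsplit(trimws(readLines(path, n = 1)), "[ \t]+")[[1]][1])
  skip <- if (first %in% c("family", "fid", "famid")) 1L else 0L
  df <- utils::read.table(path, header = FALSE, skip = skip,
                          colClasses = "character",
                          col.names = c("family", "id", "father", "mother", "sex"))
  tryCatch(
    pedigree(id = df$id, father = df$father, mother = df$mother,
             sex = df$sex, family = df$family),
    error = function(e) {
      # row numbers in messages refer to the data frame; translate to file lines
      stop("while reading ", path, " (data line = reported row + ", skip,
           "): ", conditionMessage(e), call. = FALSE)
    })
}

#' Write a pedigree to a PED-like file
#'
#' @param ped A [pedigree()].
#' @param path Output path (tab-delimited, header line).
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  out$sex <- c(male = "1", female = "2", unknown = "0")[out$sex]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(attr(x, "fidx")) & is.na(attr(x, "midx")))
  cat(sprintf("pedigree: %d individuals in %d famil%s (%d founders, max depth %d)\n",
              nrow(x), length(unique(x$family)),
              if (length(unique(x$family)) == 1) "y" else "ies",
              nf, max(attr(x, "depth"))))
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  print(object)
  print(table(sex = object$sex))
  invisible(object)
}

#' Additive relationship matrix (2 * kinship) of a pedigree
#'
#' Computes the matrix 2\eqn{\Phi} of additive genetic relationships by the
#' recursive (tabular) kinship algorithm in ancestors-first order:
#' \eqn{\phi(i,i) = (1 + \phi(f_i, m_i))/2} and
#' \eqn{\phi(i,j) = (\phi(f_i,j) + \phi(m_i,j))/2} for previously processed
#' \eqn{j}, with terms involving a missing parent equal to 0. The diagonal is
#' \eqn{1 + F_i} where \eqn{F_i} is the inbreeding coefficient; individuals
#' in different families have relationship 0. This matrix structures the
#' additive genetic covariance in the polygenic model
#' \eqn{\Omega = 2\Phi\sigma^2_a + I\sigma^2_e}.
#'
#' @param ped A [pedigree()].
#' @return Dense symmetric numeric matrix with individual ids as dimnames;
#'   entries in [0, 2], diagonal \eqn{\ge 1}, positive semidefinite.
#' @export
kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  fidx <- attr(ped, "fidx")
  midx <- attr(ped, "midx")
  ord <- order(attr(ped, "depth"))
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- fidx[i]; m <- midx[i]
    if (k > 1L) {
      prev <- ord[seq_len(k - 1L)]
      pf <- if (is.na(f)) 0 else phi[f, prev]
      pm <- if (is.na(m)) 0 else phi[m, prev]
      v <- 0.5 * (pf + pm)
      phi[i, prev] <- v
      phi[prev, i] <- v
    }
    phi[i, i] <- 0.5 * (1 + if (!is.na(f) && !is.na(m)) phi[f, m] else 0)
  }
  2 * phi
}

#' Degree of relationship between two pedigree members
#'
#' Classifies a pair by its expected additive relationship: first degree
#' (2\eqn{\phi} = 1/2: parents, offspring, full siblings), second degree
#' (1/4: half-siblings, grandparents/grandchildren, avuncular pairs, double
#' first cousins), third degree (1/8: first cousins, great-avuncular pairs),
#' otherwise `"other"`.
#'
#' @param ped A [pedigree()].
#' @param a,b Individual ids.
#' @param K Optional precomputed [kinship()] matrix for `ped`.
#' @return One of `"first"`, `"second"`, `"third"`, `"other"`.
#' @export
relative_degree <- function(ped, a, b, K = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  for (x in c(a, b)) if (!x %in% ped$id) stop("unknown individual id '", x, "'")
  if (is.null(K)) K <- kinship(ped)
  r <- K[a, b]
  tol <- 1e-9
  if (abs(r - 0.5) < tol) "first"
  else if (abs(r - 0.25) < tol) "second"
  else if (abs(r - 0.125) < tol) "third"
  else "other"
}

#' Write a relationship matrix to disk
#'
#' @param K Matrix from [kinship()].
#' @param path Output path.
#' @param format `"tsv"` (dense, id header row and column) or `"triplet"`
#'   (matrix-market-style: a `%%MatrixMarket`-headed upper-triangle
#'   coordinate list of the nonzero entries, 1-based indices in the id order
#'   given on comment lines).
#' @export
write_relmatrix <- function(K, path, format = c("tsv", "triplet")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(id = rownames(K), K, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ut <- which(upper.tri(K, diag = TRUE) & K != 0, arr.ind = TRUE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix coordinate real symmetric",
                 paste("%ids:", paste(rownames(K), collapse = " ")),
                 paste(nrow(K), ncol(K), nrow(ut))), con)
    # symmetric MM convention stores the lower triangle: emit (col,row)
    writeLines(sprintf("%d %d %.10g", ut[, 2], ut[, 1], K[ut]), con)
  }
  invisible(path)
}
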