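#' Multi-chain coordinate sets
#'
#' A chain set holds per-chain ordered residue records. Every residue has
#' a C-alpha coordinate (Angstrom); C-beta, carbonyl O, amide N and amide
#' H coordinates are optional and only needed by the operations that use
#' them (e.g. hydrogen-bond detection). This representation covers both
#' coarse-grained three-bead chains and all-atom-like backbones.
#'
#' @param chains named list; each element is a list with matrix `ca`
#'   (n x 3, required, n >= 3) and optional n x 3 matrices `cb`, `o`,
#'   `n`, `h`.
#' @param replica optional integer replica index.
#' @return Object of class `snf_chain_set`.
#' @export
chain_set <- function(chains, replica = NULL) {
  if (length(chains) < 1) snf_abort("need at least one chain", "degenerate_input")
  if (is.null(names(chains)) || any(names(chains) == ""))
    names(chains) <- LETTERS[seq_along(chains)]
  for (nm in names(chains)) {
    ch <- chains[[nm]]
    if (is.matrix(ch) || is.data.frame(ch)) {
      ch <- list(ca = as.matrix(ch))
      chains[[nm]] <- ch
    }
    if (is.null(ch$ca) || !is.matrix(ch$ca) || ncol(ch$ca) != 3)
      snf_abort(sprintf("chain %s: ca must be an n x 3 matrix", nm), "format")
    if (nrow(ch$ca) < 3)
      snf_abort(sprintf("chain %s has fewer than 3 residues", nm),
                "degenerate_input")
    if (any(!is.finite(ch$ca)))
      snf_abort(sprintf("chain %s: non-finite coordinates", nm), "nonfinite")
    for (role in c("cb", "o", "n", "h")) {
      if (!is.null(ch[[role]]) && nrow(ch[[role]]) != nrow(ch$ca))
        snf_abort(sprintf("chain %s: %s length mismatch", nm, role), "format")
    }
  }
  structure(list(chains = chains, replica = replica), class = "snf_chain_set")
}

#' @export
print.snf_chain_set <- function(x, ...) {
  nres <- vapply(x$chains, function(c) nrow(c$ca), 0L)
  cat(sprintf("<snf_chain_set: %d chains, %d residues%s>\n",
              length(x$chains), sum(nres),
              if (!is.null(x$replica)) paste0(", replica ", x$replica) else ""))
  invisible(x)
}

n_chains <- function(x) length(x$chains)

#' Read / write chain sets as minimal PDB
#'
#' Writes CA (and CB/O/N/H where present) ATOM records with chain
#' identifiers; a list of chain sets is written as a multi-MODEL file and
#' read back as replicas. Reading uses the `bio3d` PDB parser.
#'
#' @param path PDB file path.
#' @return [read_chains_pdb()] returns a `snf_chain_set`, or a list of
#'   them for a multi-model file.
#' @export
read_chains_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  one_model <- function(xyz) {
    coords <- matrix(xyz, ncol = 3, byrow = TRUE)
    chains <- list()
    for (ch in unique(at$chain)) {
      sel <- at$chain == ch
      resnos <- sort(unique(at$resno[sel]))
      get_role <- function(elety) {
        m <- matrix(NA_real_, length(resnos), 3)
        idx <- which(sel & at$elety == elety)
        m[match(at$resno[idx], resnos), ] <- coords[idx, , drop = FALSE]
        m
      }
      ca <- get_role("CA")
      if (any(is.na(ca)))
        snf_abort(sprintf("chain %s: missing CA records", ch), "format")
      entry <- list(ca = ca)
      for (role in c("CB", "O", "N", "H")) {
        m <- get_role(role)
        if (!all(is.na(m))) entry[[tolower(role)]] <- m
      }
      chains[[ch]] <- entry
    }
    chain_set(chains)
  }
  if (n_models == 1) return(one_model(pdb$xyz[1, ]))
  out <- lapply(seq_len(n_models), function(i) {
    cs <- one_model(pdb$xyz[i, ])
    cs$replica <- i
    cs
  })
  out
}

#' @rdname read_chains_pdb
#' @param x a `snf_chain_set` or list of them (replicas -> MODELs).
#' @export
write_chains_pdb <- function(x, path) {
  sets <- if (inherits(x, "snf_chain_set")) list(x) else x
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(sets) > 1
  role_name <- c(ca = "CA", cb = "CB", o = "O", n = "N", h = "H")
  for (mi in seq_along(sets)) {
    if (multi) writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    for (ch in names(sets[[mi]]$chains)) {
      entry <- sets[[mi]]$chains[[ch]]
      for (ri in seq_len(nrow(entry$ca))) {
        for (role in names(role_name)) {
          mat <- entry[[role]]
          if (is.null(mat) || any(is.na(mat[ri, ]))) next
          serial <- serial + 1L
          writeLines(sprintf(
            "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, sprintf(" %-3s", role_name[[role]]), "GLY",
            substr(ch, 1, 1), ri, mat[ri, 1], mat[ri, 2], mat[ri, 3]), con)
        }
      }
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read / write chain sets as extended XYZ
#'
#' Whitespace table with columns `atom x y z chain resid`, preceded by an
#' atom count line and a comment line.
#'
#' @param path file path.
#' @return [read_chains_xyz()] returns a `snf_chain_set`.
#' @export
read_chains_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  d <- utils::read.table(text = lines[3:(2 + n)],
                         col.names = c("atom", "x", "y", "z", "chain", "resid"))
  chains <- list()
  for (ch in unique(d$chain)) {
    dd <- d[d$chain == ch, ]
    resnos <- sort(unique(dd$resid))
    entry <- list()
    for (role in c("CA", "CB", "O", "N", "H")) {
      dr <- dd[dd$atom == role, ]
      if (nrow(dr) == 0) next
      m <- matrix(NA_real_, length(resnos), 3)
      m[match(dr$resid, resnos), ] <- as.matrix(dr[, c("x", "y", "z")])
      entry[[tolower(role)]] <- m
    }
    chains[[as.character(ch)]] <- entry
  }
  chain_set(chains)
}

#' @rdname read_chains_xyz
#' @param x a `snf_chain_set`.
#' @export
write_chains_xyz <- function(x, path) {
  stopifnot(inherits(x, "snf_chain_set"))
  rows <- character(0)
  role_name <- c(ca = "CA", cb = "CB", o = "O", n = "N", h = "H")
  for (ch in names(x$chains)) {
    entry <- x$chains[[ch]]
    for (ri in seq_len(nrow(entry$ca))) {
      for (role in names(role_name)) {
        mat <- entry[[role]]
        if (is.null(mat) || any(is.na(mat[ri, ]))) next
        rows <- c(rows, sprintf("%s %.4f %.4f %.4f %s %d", role_name[[role]],
                                mat[ri, 1], mat[ri, 2], mat[ri, 3], ch, ri))
      }
    }
  }
  writeLines(c(as.character(length(rows)),
               "extended xyz: atom x y z chain resid", rows), path)
  invisible(path)
}
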