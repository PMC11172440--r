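# Small in-code structure builders and independent oracles shared by the
# test files.

# build a MolecularStructure from short vectors
mkStruct <- function(name, el, x, y, z, resname = "LIG", resid = 1L,
                     chain = "X", role = "ligand", serial = NULL) {
  n <- max(length(name), length(x), length(y), length(z))
  name <- rep_len(name, n); el <- rep_len(el, n)
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  molecularStructure(data.frame(
    serial = if (is.null(serial)) seq_len(n) else serial,
    name = name, element = el,
    resname = rep_len(resname, n), resid = rep_len(as.integer(resid), n),
    chain = rep_len(chain, n), x = x, y = y, z = z,
    role = rep_len(role, n), stringsAsFactors = FALSE))
}

mkWaterStruct <- function(oxy, firstResid = 501L, chain = "W") {
  n <- nrow(oxy)
  molecularStructure(data.frame(
    serial = 9000L + seq_len(n), name = "O", element = "O",
    resname = "HOH", resid = firstResid + seq_len(n) - 1L, chain = chain,
    x = oxy[, 1], y = oxy[, 2], z = oxy[, 3], role = "water",
    stringsAsFactors = FALSE))
}

# single water molecule (O, H, H) with experimental-like geometry
mkWaterMolecule <- function() {
  mkStruct(c("O", "H1", "H2"), c("O", "H", "H"),
           x = c(0, 0.957, -0.24), y = c(0, 0, 0.927), z = c(0, 0, 0),
           resname = "HOH", role = "water")
}

mkMethanol <- function() {
  mkStruct(c("C", "O", "H1", "H2", "H3", "HO"),
           c("C", "O", "H", "H", "H", "H"),
           x = c(0, 1.43, -0.36, -0.36, -0.36, 1.75),
           y = c(0, 0, 1.03, -0.51, -0.51, 0.9),
           z = c(0, 0, 0, 0.89, -0.89, 0))
}

mkEthylamine <- function() {
  mkStruct(c("C1", "C2", "N", "H1", "H2", "H3", "H4", "H5", "H6", "H7"),
           c("C", "C", "N", rep("H", 7)),
           x = c(0, 1.53, 2.05, -0.38, -0.38, -0.38, 1.91, 1.91, 1.75, 1.75),
           y = c(0, 0, 1.38, -0.52, -0.52, 1.03, -0.52, -0.52, 1.9, 1.9),
           z = c(0, 0, 0, 0.88, -0.88, 0, 0.88, -0.88, 0.8, -0.8))
}

# independent quaternion-eigenvalue superposition oracle (Horn 1987):
# minimal RMSD of Q onto P over proper rotations + translation
quaternionRmsd <- function(P, Q) {
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  S <- t(Pc) %*% Qc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lmax) / n
  sqrt(max(msd, 0))
}

# random proper rotation matrix
randomRotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr <- qr(M)
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

toyRoleMap <- c(A = "target", B = "ligand")
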