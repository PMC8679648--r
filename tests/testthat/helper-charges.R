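# Reference DDEC point charges (continuum-solvent quantum calculations) for
# the eleven parametrization molecules, one entry per populated table cell.
# Roles: Si, CH3_Si / CH2_Si (alkyl on silicon), CH3_CH2Si (terminal methyl
# of an ethyl on silicon), O (any oxygen type), H (hydroxyl hydrogen),
# CHx_O (alkyl on an alkoxy oxygen), CH3_CH2O (terminal methyl of ethoxy).
ddecReference <- function() {
  rbind(
    data.frame(molecule = "Met4Si", role = c("Si", "CH3_Si"),
               ddec = c(0.960, -0.240)),
    data.frame(molecule = "Eth4Si", role = c("Si", "CH2_Si", "CH3_CH2Si"),
               ddec = c(0.975, -0.2875, 0.0438)),
    data.frame(molecule = "Met3SiOH", role = c("Si", "CH3_Si", "O", "H"),
               ddec = c(1.451, -0.329, -0.908, 0.444)),
    data.frame(molecule = "Eth3SiOH",
               role = c("Si", "CH2_Si", "CH3_CH2Si", "O", "H"),
               ddec = c(1.237, -0.333, 0.0605, -0.849, 0.4295)),
    data.frame(molecule = "Met6Si2O", role = c("Si", "CH3_Si", "O"),
               ddec = c(1.458, -0.3335, -0.915)),
    data.frame(molecule = "SiOMet4", role = c("Si", "O", "CHx_O"),
               ddec = c(1.852, -0.719, 0.256)),
    data.frame(molecule = "SiOEth4", role = c("Si", "O", "CHx_O", "CH3_CH2O"),
               ddec = c(1.878, -0.758, 0.326, -0.0375)),
    data.frame(molecule = "M3SiOE",
               role = c("Si", "CH3_Si", "O", "CHx_O", "CH3_CH2O"),
               ddec = c(1.390, -0.320, -0.678, 0.294, -0.046)),
    data.frame(molecule = "M2ESiOE",
               role = c("Si", "CH3_Si", "CH2_Si", "CH3_CH2Si", "O", "CHx_O",
                        "CH3_CH2O"),
               ddec = c(1.329, -0.319, -0.332, 0.0583, -0.664, 0.2915, -0.0448)),
    data.frame(molecule = "ME2SiOE",
               role = c("Si", "CH3_Si", "CH2_Si", "CH3_CH2Si", "O", "CHx_O",
                        "CH3_CH2O"),
               ddec = c(1.258, -0.309, -0.3282, 0.0519, -0.645, 0.289, -0.0404)),
    data.frame(molecule = "E3SiOE",
               role = c("Si", "CH2_Si", "CH3_CH2Si", "O", "CHx_O", "CH3_CH2O"),
               ddec = c(1.194, -0.322, 0.0554, -0.638, 0.287, -0.0432)))
}

# classify each site of a typed united-atom graph into the reference roles
# and return the model charge per role present
modelChargesByRole <- function(name, params = defaultParameters()) {
  g <- assignAtomTypes(perceiveUnitedAtoms(siliconMolecule(name)))
  q <- assignCharges(g, params)
  adj <- lapply(seq_along(g@types), function(i) {
    b <- g@bonds
    c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
  })
  ty <- g@types
  role <- rep(NA_character_, length(ty))
  for (i in seq_along(ty)) {
    t <- ty[i]
    nbt <- ty[adj[[i]]]
    role[i] <-
      if (t == "Si") "Si"
      else if (t == "H_O") "H"
      else if (t %in% c("O_C", "O_H", "O_B")) "O"
      else if (t == "CH3" && any(nbt == "Si")) "CH3_Si"
      else if (t == "CH2" && any(nbt == "Si")) "CH2_Si"
      else if (any(nbt == "O_C")) "CHx_O"
      else if (t == "CH3" && any(nbt == "CH2")) {
        ch2 <- adj[[i]][nbt == "CH2"][1]
        nb2 <- ty[adj[[ch2]]]
        if (any(nb2 == "Si")) "CH3_CH2Si"
        else if (any(nb2 == "O_C")) "CH3_CH2O"
        else NA_character_
      } else NA_character_
  }
  vapply(split(q[!is.na(role)], role[!is.na(role)]), mean, 0)
}
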