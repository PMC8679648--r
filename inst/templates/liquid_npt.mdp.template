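; Liquid-phase NpT run-configuration template (documentation only; not
; executed by the package).  Parametrization runs: 10 ns; validation runs:
; 50 ns; silanol-containing molecules run twice as long (20 / 100 ns).
; First 0.5 ns discarded for equilibration.
integrator               = md
dt                       = 0.002        ; 2 fs
nsteps                   = 25000000     ; set per run length
cutoff-scheme            = Verlet
rlist                    = 1.0
vdwtype                  = Cut-off
rvdw                     = 1.0          ; 1.0 nm LJ cutoff
DispCorr                 = EnerPres     ; long-range dispersion corrections
coulombtype              = PME          ; particle-mesh Ewald
rcoulomb                 = 1.0
tcoupl                   = V-rescale
tc-grps                  = System
tau-t                    = 0.1          ; ps
ref-t                    = 298
pcoupl                   = Parrinello-Rahman
tau-p                    = 2.0          ; ps
compressibility          = 4.5e-5
ref-p                    = 1.0          ; bar
constraints              = all-bonds    ; rigid bonds
constraint-algorithm     = LINCS
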