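; Gas-phase (single molecule, vacuum) NVT run-configuration template
; (documentation only).  Same protocol as the liquid runs except: no
; barostat, one molecule, no periodic boundary conditions or cutoffs.
integrator               = md
dt                       = 0.002
nsteps                   = 25000000
pbc                      = no
cutoff-scheme            = group
rlist                    = 0
rvdw                     = 0
rcoulomb                 = 0
coulombtype              = Cut-off
tcoupl                   = V-rescale
tc-grps                  = System
tau-t                    = 0.1
ref-t                    = 298
pcoupl                   = no
constraints              = all-bonds
constraint-algorithm     = LINCS
comm-mode                = Angular
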