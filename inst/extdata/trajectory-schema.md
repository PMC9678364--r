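# Trajectory file schema (format "actoring-trajectory", version 1)

A trajectory is a single JSON object:

    {
      "format":  "actoring-trajectory",
      "version": 1,
      "status":  "completed" | "stopped" | "frozen" | "synthetic",
      "snapshots": [ <snapshot>, ... ]
    }

Each snapshot:

    {
      "time":        <s>,
      "n_filaments": <int>,
      "filaments": [
        { "verts":  [[x,y,z], ...],   # cylinder endpoints, nm,
                                      # pointed end first, m+1 rows
          "nmono":  [n1, ..., nm],    # monomers per cylinder (1..40)
          "barbed": "BE" | "FBE" },   # free or formin-bound barbed end
        ...
      ],
      "motors":  { "fa","ca","sa","fb","cb","sb","l0","n_heads" },
                   # column arrays; (fa,ca,sa) = filament index within
                   # this snapshot, cylinder index, site index (1..4);
                   # l0 = spring rest length, nm
      "linkers": { "fa","ca","sa","fb","cb","sb","l0" },
      "grid_counts": [[G, formin, intermediate, NMII, linker], ...]
                   # per-compartment copy numbers (one row per
                   # compartment; a single row for well-mixed runs)
      "counters": { "be_add","be_rem","pe_add","pe_rem",
                    "nuc","destr","forced_unbind" },
                   # cumulative end-event counters, monotone in time
      "energy":  { "U_fil_str","U_fil_bend","U_vol","U_motor_str",
                   "U_linker_str","U_boundary","U_total" },  # pN nm
      "labeled": { "n", "n0" } | null,  # FRAP-like labeled monomers
      "geom":    { "shape","diameter_nm","height_nm","a0_nm",
                   "R_eff","half_height_eff" }
    }

Numbers are written with 17 significant digits, so reading a file back
reproduces the in-memory doubles exactly.
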