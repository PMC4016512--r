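>CLV3 real dodecapeptide (CLAVATA3)
RTVPSGPDPLHH
>CLE13 real dodecapeptide
RLVPSGPNPLHH
>CLE41_44 real dodecapeptide (TDIF)
HEVPSGPNPISN
>SYN04 synthetic CLE-like dodecamer
RTVPSGPDPLGP
>SYN05 synthetic CLE-like dodecamer
KLVPSGPDPIGH
>SYN06 synthetic CLE-like dodecamer
KLVPSGPNPRGY
>SYN07 synthetic CLE-like dodecamer
RTVPSGPDPLNY
>SYN08 synthetic CLE-like dodecamer
KVVPSGPNPIRN
>SYN09 synthetic CLE-like dodecamer
KSVPSGPDPRSP
>SYN10 synthetic CLE-like dodecamer
RSVPSGPNPRNP
>SYN11 synthetic CLE-like dodecamer
HTVPSGPNPLHR
>SYN12 synthetic CLE-like dodecamer
KEVPSGPDPLQY
>SYN13 synthetic CLE-like dodecamer
RSVPSGPDPRQP
>SYN14 synthetic CLE-like dodecamer
RLVPSGPNPKNN
>SYN15 synthetic CLE-like dodecamer
HVVPSGPDPTQY
>SYN16 synthetic CLE-like dodecamer
RLVPSGPDPQGN
>SYN17 synthetic CLE-like dodecamer
RLVPSGPDPRRP
>SYN18 synthetic CLE-like dodecamer
KVVPSGPDPQRN
>SYN19 synthetic CLE-like dodecamer
KSVPSGPDPQSH
>SYN20 synthetic CLE-like dodecamer
RTVPSGPNPTNP
>SYN21 synthetic CLE-like dodecamer
RTVPSGPNPINH
>SYN22 synthetic CLE-like dodecamer
HLVPSGPNPINY
>SYN23 synthetic CLE-like dodecamer
HSVPSGPDPTQR
>SYN24 synthetic CLE-like dodecamer
HLVPSGPDPTQY
>SYN25 synthetic CLE-like dodecamer
HSVPSGPNPIGY
>SYN26 synthetic CLE-like dodecamer
RSVPSGPNPQGN
>SYN27 synthetic CLE-like dodecamer
KEVPSGPDPKRN
>SYN28 synthetic CLE-like dodecamer
HSVPSGPDPLNR
>SYN29 synthetic CLE-like dodecamer
HSVPSGPDPRQH
>SYN30 synthetic CLE-like dodecamer
KVVPSGPNPQHH
>SYN31 synthetic CLE-like dodecamer
KLVPSGPNPLNP
>SYN32 synthetic CLE-like dodecamer
RTVPSGPNPIGH
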