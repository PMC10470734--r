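>seed01
RQMPKDSCKRVPFTKIDRCCCSNKNNIDPYRAHTCHMHHSEMCCKDTGVYPKQDP
>seed02
AQMDVDSMNRCPFQKIYRCKCSNKVNIDGYRPIKCQMYHSLYCCLDTGHNVHQDP
>seed03
SQMPKDSCKRACFTKIYRCKCILKNNIDGYRMHKCHMYHSEYCCLATGHNPHYDP
>seed04
AQMPKDKCKRVPFVKIYRCKCSNKNNIDGYRMHKCHMYHSEYCCLDTGHNPKQIP
>seed05
AQMPKDSCKRVPFTKIYKCICSNKNNIDGYRMHKCHSYLSEHCCLYTYGNPHQDP
>seed06
AQMPKDSCKRVPFTKIYRCKCSNKINIDGYRMHKCHMYVSEYCCLDTTHNPHHDP
>seed07
AQMPKDMCKRVPFTKIYKCKCSNKNNIDGYRMHKCHMYHSEYCCLGTGHNPHQDP
>seed08
ARMPKDQCKRVPSTKIYSCKCYNYNNIDGYRMHVCHMYHSEYCSLDTGHNPHQDP
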